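#' @export
setGeneric("alignments", function(x, ...) standardGeneric("alignments"))

#' Extract the alignment GRanges
#'
#' @param x a \code{\linkS4class{ReadAlignments}} object.
#' @param ... unused.
#' @return \code{GRanges} with metadata columns \code{read_id},
#'   \code{mismatches}, \code{weight}.
#' @export
setMethod("alignments", "ReadAlignments", function(x, ...) x@alignments)

#' @export
setGeneric("isWeighted", function(x) standardGeneric("isWeighted"))

#' Has allocation been run?
#' @param x a \code{ReadAlignments} object.
#' @return logical scalar.
#' @export
setMethod("isWeighted", "ReadAlignments", function(x) x@weighted)

#' @export
setGeneric("binData", function(x, ...) standardGeneric("binData"))

#' Bin table as a data.frame
#'
#' @param x a \code{\linkS4class{BinTable}}.
#' @param ... unused.
#' @return data.frame with columns chrom, start (1-based), end,
#'   chip_fractional, chip_count, input_count, mappability, gc.
#' @export
setMethod("binData", "BinTable", function(x, ...) {
    gr <- x@bins
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr),
               as.data.frame(S4Vectors::mcols(gr)),
               stringsAsFactors = FALSE)
})

#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' Bin width of a BinTable
#' @param x a \code{BinTable}.
#' @return integer bin width in bp.
#' @export
setMethod("binSize", "BinTable", function(x) x@binSize)

#' @export
setGeneric("binRanges", function(x) standardGeneric("binRanges"))

#' Bin tiling of a BinTable
#' @param x a \code{BinTable}.
#' @return the \code{GRanges} tiling with its count/covariate columns.
#' @export
setMethod("binRanges", "BinTable", function(x) x@bins)

#' @export
setGeneric("posteriorProb", function(x) standardGeneric("posteriorProb"))

#' Per-bin posterior probability of binding
#' @param x an \code{NBMixtureFit}.
#' @return numeric vector aligned with the fitted bin table.
#' @export
setMethod("posteriorProb", "NBMixtureFit", function(x) x@posterior)

#' @export
setGeneric("windowSum", function(x, chrom, p, w) standardGeneric("windowSum"))

#' @export
setGeneric("mappabilityScores", function(x) standardGeneric("mappabilityScores"))

#' Per-chromosome mappability score vectors
#' @param x a \code{MappabilityTrack}.
#' @return named list of numeric vectors.
#' @export
setMethod("mappabilityScores", "MappabilityTrack", function(x) x@scores)
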