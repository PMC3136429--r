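#' Candidate (optionally weighted) read alignments
#'
#' Container for the candidate alignments of a set of sequencing tags.  Each
#' alignment is one row of a \link[GenomicRanges]{GRanges} with metadata
#' columns \code{read_id} (character), \code{mismatches} (integer) and
#' \code{weight} (numeric; \code{NA} until allocation has been run).  A read
#' with exactly one alignment is a uni-read; reads with several candidate
#' alignments are multi-reads and their weights, once allocated, sum to one.
#'
#' @slot alignments \code{GRanges} of candidate alignments with metadata
#'   columns \code{read_id}, \code{mismatches}, \code{weight}.
#' @slot readLength integer tag length in bp.
#' @slot weighted logical; \code{TRUE} after allocation.
#'
#' @seealso \code{\link{readAlignmentFile}}, \code{\link{allocateMultiReads}}
#' @export
setClass("ReadAlignments",
    representation(alignments = "GRanges",
                   readLength = "integer",
                   weighted   = "logical"),
    prototype(readLength = NA_integer_, weighted = FALSE))

setValidity("ReadAlignments", function(object) {
    gr <- object@alignments
    mc <- S4Vectors::mcols(gr)
    need <- c("read_id", "mismatches", "weight")
    if (!all(need %in% colnames(mc)))
        return(sprintf("alignments must carry metadata columns %s",
                       paste(need, collapse = ", ")))
    if (length(gr) == 0L) return(TRUE)
    if (any(GenomicRanges::start(gr) < 1L))
        return("alignment start < 1")
    if (object@weighted) {
        w <- mc$weight
        if (anyNA(w)) return("weighted object has NA weights")
        if (any(w < -1e-9 | w > 1 + 1e-9))
            return("weights outside [0, 1]")
        s <- rowsum(w, mc$read_id)
        if (any(abs(s - 1) > 1e-5))
            return("per-read weights do not sum to 1")
    }
    TRUE
})

#' Sparse fractional count index with O(log n) window sums
#'
#' Stores fractional read counts at the genomic positions where at least one
#' alignment starts, one Fenwick (binary indexed) tree per chromosome, so
#' that point updates and interval sums both cost O(log n) in the number of
#' stored positions.  This is the count store used by the iterative
#' multi-read allocation.
#'
#' @slot store environment mapping chromosome name to a list with elements
#'   \code{pos} (sorted integer positions) and \code{tree} (numeric Fenwick
#'   array over those positions).
#'
#' @seealso \code{\link{countIndex}}, \code{\link{windowSum}}
#' @export
setClass("CountIndex", representation(store = "environment"))

#' Per-position genome mappability track
#'
#' Mappability of a tag start position x is derived from n(x), the number of
#' times the k-mer starting at x occurs in the genome (both strands).
#' Definition \code{"def1"} (uni-read mappability) scores 1 iff n(x) = 1;
#' definition \code{"def2"} (multi-read-aware) scores 1/n(x) when
#' n(x) < \code{cap} (default 100 candidate locations, beyond which reads are
#' discarded) and 0 otherwise.  Fragment extension averages the per-start
#' scores over all tag start positions, on either strand, whose L-bp extended
#' fragment covers a position.
#'
#' @slot scores named list, one numeric vector per chromosome (full
#'   chromosome length; positions that cannot start a full k-mer score 0).
#' @slot definition \code{"def1"} or \code{"def2"}.
#' @slot k integer tag length.
#' @slot extended logical; \code{TRUE} after fragment extension.
#' @slot fragLength integer fragment length L when extended, otherwise NA.
#'
#' @seealso \code{\link{nucleotideMappability}},
#'   \code{\link{fragmentExtendMappability}}
#' @export
setClass("MappabilityTrack",
    representation(scores = "list", definition = "character",
                   k = "integer", extended = "logical",
                   fragLength = "integer"),
    prototype(extended = FALSE, fragLength = NA_integer_))

setValidity("MappabilityTrack", function(object) {
    if (!object@definition %in% c("def1", "def2"))
        return("definition must be 'def1' or 'def2'")
    rng <- range(unlist(object@scores, use.names = FALSE), 0, 1)
    if (rng[1] < 0 || rng[2] > 1) return("scores outside [0, 1]")
    if (!object@extended && object@definition == "def1") {
        v <- unlist(object@scores, use.names = FALSE)
        if (length(v) && !all(v %in% c(0, 1)))
            return("unextended def1 scores must be 0/1")
    }
    TRUE
})

#' Bin-level ChIP/input count table
#'
#' Non-overlapping genome tiling bins with fractional and integer ChIP
#' counts, input counts, mean mappability and GC content: the common input
#' of both peak callers.  Bins consisting only of the ambiguous base N are
#' excluded at construction.
#'
#' @slot bins \code{GRanges} tiling with metadata columns
#'   \code{chip_fractional}, \code{chip_count}, \code{input_count},
#'   \code{mappability}, \code{gc}.
#' @slot binSize integer bin width in bp.
#' @slot rounding how fractional ChIP counts were made integer
#'   (\code{"round"}, \code{"ceiling"} or \code{"floor"}).
#'
#' @seealso \code{\link{extendAndBin}}, \code{\link{assembleBinTable}}
#' @export
setClass("BinTable",
    representation(bins = "GRanges", binSize = "integer",
                   rounding = "character"))

setValidity("BinTable", function(object) {
    mc <- S4Vectors::mcols(object@bins)
    need <- c("chip_fractional", "chip_count", "input_count",
              "mappability", "gc")
    miss <- setdiff(need, colnames(mc))
    if (length(miss))
        return(sprintf("missing bin columns: %s", paste(miss, collapse = ", ")))
    if (length(object@bins) &&
        any(GenomicRanges::width(object@bins) > object@binSize))
        return("bin wider than binSize")
    ol <- GenomicRanges::findOverlaps(object@bins, drop.self = TRUE)
    if (length(ol)) return("bins overlap")
    TRUE
})

#' Fitted two-component negative-binomial mixture
#'
#' Result of \code{\link{fitNBMixture}}: background bins follow a negative
#' binomial whose mean is log-linear in mappability, a piecewise-linear GC
#' spline (knots at the GC 1st/3rd quartiles) and log(1 + input count);
#' bound bins follow the background shifted by a minimum bound count plus a
#' mixture of two negative binomials.  Posterior probabilities of binding
#' drive direct posterior-probability FDR control in
#' \code{\link{callPeaks}}.
#'
#' @slot coefficients named numeric background regression coefficients.
#' @slot theta numeric background NB dispersion (size).
#' @slot mixprop numeric proportion of bound bins.
#' @slot signal list with the two signal components (\code{mu}, \code{size},
#'   \code{prop}) and the shift constant.
#' @slot posterior numeric per-bin posterior probability of binding.
#' @slot gcKnots numeric GC spline knots used.
#' @slot converged logical.
#' @slot iterations integer EM iterations run.
#'
#' @export
setClass("NBMixtureFit",
    representation(coefficients = "numeric", theta = "numeric",
                   mixprop = "numeric", signal = "list",
                   posterior = "numeric", gcKnots = "numeric",
                   converged = "logical", iterations = "integer"))

setMethod("show", "ReadAlignments", function(object) {
    gr <- object@alignments
    ids <- S4Vectors::mcols(gr)$read_id
    k <- table(ids)
    cat("ReadAlignments with", length(gr), "alignments of",
        length(k), "reads\n")
    cat("  uni-reads:", sum(k == 1L), " multi-reads:", sum(k > 1L), "\n")
    cat("  read length:", object@readLength,
        " weighted:", object@weighted, "\n")
})

setMethod("show", "CountIndex", function(object) {
    chroms <- ls(object@store)
    n <- sum(vapply(chroms, function(ch) length(object@store[[ch]]$pos), 0L))
    cat("CountIndex over", n, "stored positions on",
        length(chroms), "chromosome(s)\n")
})

setMethod("show", "MappabilityTrack", function(object) {
    cat("MappabilityTrack (", object@definition, ", k = ", object@k,
        if (object@extended) paste0(", fragment-extended L = ",
                                    object@fragLength) else "",
        ") over ", length(object@scores), " chromosome(s)\n", sep = "")
})

setMethod("show", "BinTable", function(object) {
    cat("BinTable with", length(object@bins), "bins of",
        object@binSize, "bp (rounding:", object@rounding, ")\n")
    if (length(object@bins)) {
        mc <- S4Vectors::mcols(object@bins)
        cat("  total ChIP:", sum(mc$chip_count),
            " total input:", sum(mc$input_count), "\n")
    }
})

setMethod("show", "NBMixtureFit", function(object) {
    cat("NBMixtureFit:", length(object@posterior), "bins,",
        object@iterations, "EM iterations",
        if (object@converged) "(converged)" else "(not converged)", "\n")
    cat("  bound proportion:", signif(object@mixprop, 4),
        " background theta:", signif(object@theta, 4), "\n")
    print(signif(object@coefficients, 4))
})
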