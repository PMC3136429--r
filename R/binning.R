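.roundCounts <- function(x, rounding) {
    switch(rounding,
        round = floor(x + 0.5),   # half away from zero (counts are >= 0)
        ceiling = ceiling(x),
        floor = floor(x),
        stop("unknown rounding rule: ", rounding))
}

#' Fragment-extend weighted alignments and accumulate bin counts
#'
#' Each alignment is extended strand-aware to the expected fragment length
#' (forward: \code{[start, start + L - 1]}; reverse: \code{[end - L + 1,
#' end]}, clipped at chromosome boundaries) and its allocation weight is
#' added to every bin its fragment overlaps.  In \code{"UR"} mode only
#' uni-reads are used (each with weight 1); in \code{"MR"} mode uni-reads
#' and allocated multi-reads contribute, multi-reads fractionally in
#' proportion to their alignment weights.  Final integer counts are obtained
#' from the fractional sums with the requested rounding rule ("round" is
#' half-away-from-zero).
#'
#' @param x a weighted \code{\linkS4class{ReadAlignments}}.
#' @param seqlens named integer vector of chromosome lengths, or a
#'   \code{DNAStringSet} genome.
#' @param binSize bin width in bp (default 200, matched to the expected
#'   fragment length; the usual working range is 50-250 bp and values
#'   outside it warn).
#' @param fragLength fragment length L (default 200).
#' @param mode \code{"MR"} (uni + multi) or \code{"UR"} (uni-reads only).
#' @param rounding \code{"round"}, \code{"ceiling"} or \code{"floor"}.
#' @return \code{GRanges} tiling with metadata columns \code{fractional}
#'   and \code{count}.
#' @export
extendAndBin <- function(x, seqlens, binSize = 200L, fragLength = 200L,
                         mode = c("MR", "UR"),
                         rounding = c("round", "ceiling", "floor")) {
    mode <- match.arg(mode)
    rounding <- match.arg(rounding)
    stopifnot(is(x, "ReadAlignments"))
    if (!isWeighted(x)) stop("alignments must be weighted (run allocation)")
    if (binSize < 50L || binSize > 250L)
        warning("bin size ", binSize, " is outside the usual 50-250 bp range")
    if (is(seqlens, "DNAStringSet")) seqlens <- .seqlens(seqlens)
    gr <- alignments(x)
    mc <- S4Vectors::mcols(gr)
    if (mode == "UR") {
        k <- table(mc$read_id)
        keep <- mc$read_id %in% names(k)[k == 1L]
        gr <- gr[keep]
        mc <- S4Vectors::mcols(gr)
    }
    bins <- .binTiling(seqlens, binSize)
    frac <- numeric(length(bins))
    if (length(gr)) {
        chrom <- as.character(GenomicRanges::seqnames(gr))
        lens <- seqlens[chrom]
        fwd <- as.character(GenomicRanges::strand(gr)) != "-"
        fs <- ifelse(fwd, GenomicRanges::start(gr),
                     GenomicRanges::end(gr) - fragLength + 1L)
        fe <- fs + fragLength - 1L
        fs <- pmax(fs, 1L)
        fe <- pmin(fe, lens)
        b1 <- (fs - 1L) %/% binSize
        b2 <- (fe - 1L) %/% binSize
        # global bin index offsets per chromosome (tiling order)
        nb <- ceiling(seqlens / binSize)
        offs <- setNames(c(0L, cumsum(nb))[seq_along(nb)], names(nb))
        idx <- integer(0); wts <- numeric(0)
        for (o in 0:max(b2 - b1)) {
            sel <- b1 + o <= b2
            if (!any(sel)) break
            idx <- c(idx, offs[chrom[sel]] + b1[sel] + o + 1L)
            wts <- c(wts, mc$weight[sel])
        }
        acc <- rowsum(wts, idx)
        frac[as.integer(rownames(acc))] <- acc[, 1L]
    }
    S4Vectors::mcols(bins)$fractional <- frac
    S4Vectors::mcols(bins)$count <- as.integer(.roundCounts(frac, rounding))
    S4Vectors::metadata(bins)$binning <- list(binSize = as.integer(binSize),
        fragLength = as.integer(fragLength), mode = mode,
        rounding = rounding)
    bins
}

#' Join ChIP, input, mappability and GC bin tracks into a BinTable
#'
#' Inner-joins the four per-bin tracks on (chromosome, start, end).  All
#' tracks must come from the identical tiling; the GC track (which excludes
#' all-N bins) determines the retained bin set.  A shifted or mismatched
#' tiling is an error.
#'
#' @param chipBins,inputBins output of \code{\link{extendAndBin}} for the
#'   ChIP and input samples.
#' @param mapBins \code{GRanges} from
#'   \code{binScores(<MappabilityTrack>, binSize)}.
#' @param gcBins \code{GRanges} from \code{binScores(<DNAStringSet>,
#'   binSize)}.
#' @return a \code{\linkS4class{BinTable}}.
#' @export
assembleBinTable <- function(chipBins, inputBins, mapBins, gcBins) {
    key <- function(gr) paste(GenomicRanges::seqnames(gr),
                              GenomicRanges::start(gr),
                              GenomicRanges::end(gr), sep = ":")
    kg <- key(gcBins)
    mi <- match(kg, key(inputBins))
    mm <- match(kg, key(mapBins))
    mc <- match(kg, key(chipBins))
    if (anyNA(mc) || anyNA(mi) || anyNA(mm))
        stop("bin tilings do not match; all tracks must use the same ",
             "bin size and chromosome lengths")
    bins <- GenomicRanges::granges(gcBins)
    meta <- S4Vectors::metadata(chipBins)$binning
    S4Vectors::mcols(bins) <- S4Vectors::DataFrame(
        chip_fractional = S4Vectors::mcols(chipBins)$fractional[mc],
        chip_count = S4Vectors::mcols(chipBins)$count[mc],
        input_count = S4Vectors::mcols(inputBins)$count[mi],
        mappability = S4Vectors::mcols(mapBins)$score[mm],
        gc = S4Vectors::mcols(gcBins)$score)
    new("BinTable", bins = bins,
        binSize = if (!is.null(meta)) meta$binSize else
            as.integer(max(GenomicRanges::width(bins))),
        rounding = if (!is.null(meta)) meta$rounding else "round")
}
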