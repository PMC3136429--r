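#' Build a sparse fractional count index
#'
#' Creates a \linkS4class{CountIndex} over the given genomic positions.  Only
#' positions at which at least one alignment starts need to be stored; window
#' sums over unstored positions are implicitly zero.  Counts can be seeded
#' with \code{counts} (default all zero) and later changed with
#' \code{\link{indexAdd}} in O(log n) per update.
#'
#' @param chrom character vector of chromosome names (parallel to \code{pos}),
#'   or a \code{GRanges} whose start positions are used.
#' @param pos integer positions (1-based); ignored when \code{chrom} is a
#'   \code{GRanges}.
#' @param counts optional numeric initial counts parallel to the input
#'   positions; duplicated positions accumulate.
#' @return a \code{CountIndex}.
#' @examples
#' ci <- countIndex(c("chr1", "chr1"), c(10L, 50L), counts = c(1, 2))
#' windowSum(ci, "chr1", 30, 25)  # 3: both positions in [5, 55]
#' @export
countIndex <- function(chrom, pos = NULL, counts = NULL) {
    if (is(chrom, "GRanges")) {
        pos <- GenomicRanges::start(chrom)
        chrom <- as.character(GenomicRanges::seqnames(chrom))
    }
    chrom <- as.character(chrom)
    pos <- as.integer(pos)
    stopifnot(length(chrom) == length(pos))
    if (is.null(counts)) counts <- numeric(length(pos))
    stopifnot(length(counts) == length(pos))
    store <- new.env(parent = emptyenv())
    for (ch in unique(chrom)) {
        sel <- chrom == ch
        p <- pos[sel]
        cnt <- counts[sel]
        up <- sort(unique(p))
        acc <- numeric(length(up))
        idx <- match(p, up)
        if (any(cnt != 0)) acc <- as.numeric(rowsum(cnt, idx)[, 1L])
        store[[ch]] <- list(pos = up, tree = fenwick_build_(acc))
    }
    new("CountIndex", store = store)
}

#' Add to the count at a stored position
#'
#' @param x a \code{CountIndex}.
#' @param chrom chromosome name.
#' @param pos stored position (must be one of the positions the index was
#'   built over).
#' @param delta numeric amount to add (may be negative; counts must remain
#'   nonnegative).
#' @return the index, invisibly (modified in place).
#' @export
indexAdd <- function(x, chrom, pos, delta) {
    stopifnot(is(x, "CountIndex"))
    ent <- x@store[[chrom]]
    if (is.null(ent)) stop("unknown chromosome: ", chrom)
    i <- findInterval(pos, ent$pos)
    if (i < 1L || ent$pos[i] != pos)
        stop("position ", pos, " is not stored in the index")
    fenwick_update_(ent$tree, i, delta)
    invisible(x)
}

#' Windowed count sum around a position
#'
#' Sum of stored fractional counts over the closed window
#' \eqn{[p - w, p + w]} on one chromosome, intersected with the stored
#' positions; O(log n).
#'
#' @param x a \code{CountIndex}.
#' @param chrom chromosome name; unknown chromosomes return 0 with a warning.
#' @param p center position.
#' @param w window half-width in bp.
#' @return numeric count sum.
#' @export
setMethod("windowSum", "CountIndex", function(x, chrom, p, w) {
    ent <- x@store[[chrom]]
    if (is.null(ent)) {
        warning("unknown chromosome '", chrom, "'; returning 0")
        return(0)
    }
    lo <- findInterval(p - w - 1L, ent$pos) + 1L  # first pos >= p - w
    hi <- findInterval(p + w, ent$pos)            # last pos <= p + w
    if (hi < lo) return(0)
    fenwick_prefix_(ent$tree, hi) - fenwick_prefix_(ent$tree, lo - 1L)
})
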