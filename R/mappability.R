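#' Count k-mer occurrences at every tag start position
#'
#' For every position x that can host a full k-mer, n(x) is the number of
#' times that k-mer occurs in the genome, counting both strands (i.e.
#' occurrences of the k-mer plus occurrences of its reverse complement on
#' the forward strands of all chromosomes).  Positions whose k-mer contains
#' an ambiguous base, and the trailing k-1 positions of each chromosome,
#' get the sentinel 0.
#'
#' @param genome \code{DNAStringSet}.
#' @param k tag length (bp).
#' @return named list of integer vectors, one per chromosome, each of full
#'   chromosome length.
#' @export
kmerOccurrences <- function(genome, k) {
    k <- as.integer(k)
    if (k <= 0L) stop("k must be positive")
    chs <- names(genome)
    per <- lapply(chs, function(ch) {
        s <- as.character(genome[[ch]])
        len <- nchar(s)
        if (len < k) return(character(0))
        substring(s, seq_len(len - k + 1L), k:len)
    })
    names(per) <- chs
    all_k <- unlist(per, use.names = FALSE)
    valid <- !grepl("[^ACGT]", all_k)
    u <- unique(all_k[valid])
    cnt <- tabulate(match(all_k[valid], u), nbins = length(u))
    rcu <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(u)))
    rc_cnt <- cnt[match(rcu, u)]
    rc_cnt[is.na(rc_cnt)] <- 0L
    total <- cnt + rc_cnt
    lens <- .seqlens(genome)
    lapply(setNames(chs, chs), function(ch) {
        len <- lens[[ch]]
        n <- integer(len)
        km <- per[[ch]]
        if (length(km)) {
            m <- match(km, u)          # NA for k-mers containing N
            v <- total[m]
            v[is.na(v)] <- 0L
            n[seq_along(km)] <- v
        }
        n
    })
}

#' Nucleotide-level mappability from occurrence counts
#'
#' Definition \code{"def1"} (uni-read mappability): 1 iff the k-mer at the
#' position is unique in the genome.  Definition \code{"def2"}
#' (multi-read-aware): 1/n(x) when the k-mer occurs at fewer than \code{cap}
#' locations (reads hitting \code{cap} or more locations are discarded and
#' generate no counts), otherwise 0.
#'
#' @param occurrences list of per-chromosome occurrence counts from
#'   \code{\link{kmerOccurrences}}.
#' @param definition \code{"def1"} or \code{"def2"}.
#' @param k tag length the occurrences were computed for.
#' @param cap occurrence count at and above which def2 scores 0
#'   (default 100).
#' @return a \code{\linkS4class{MappabilityTrack}}.
#' @export
nucleotideMappability <- function(occurrences, definition = c("def1", "def2"),
                                  k, cap = 100L) {
    definition <- match.arg(definition)
    scores <- lapply(occurrences, function(n) {
        if (definition == "def1") as.numeric(n == 1L)
        else ifelse(n >= 1L & n < cap, 1 / n, 0)
    })
    new("MappabilityTrack", scores = scores, definition = definition,
        k = as.integer(k), extended = FALSE)
}

#' Fragment-extend a mappability track
#'
#' After fragment extension to length L, the count observed at position x
#' can originate from forward-strand tags starting at any of the L positions
#' ending at x, or reverse-strand tags starting (5' end) at any of the L
#' positions from x onward.  The extended score at x is therefore the mean
#' of the per-start scores over all such in-genome start positions (up to
#' 2L of them; truncated ranges at chromosome ends divide by the actual
#' number of contributing starts).  The reverse-strand score of a start s is
#' the forward score at s - k + 1, because both-strand occurrence counting
#' makes a k-mer and its reverse complement equally frequent.
#'
#' @param track an unextended \code{MappabilityTrack}.
#' @param L fragment length (bp, must be >= k).
#' @return an extended \code{MappabilityTrack}.
#' @export
fragmentExtendMappability <- function(track, L) {
    stopifnot(is(track, "MappabilityTrack"))
    if (track@extended) stop("track is already fragment-extended")
    k <- track@k
    L <- as.integer(L)
    if (L < k) stop("fragment length L must be at least the tag length k")
    scores <- lapply(track@scores, function(M) {
        len <- length(M)
        if (len == 0L) return(M)
        cm <- c(0, cumsum(M))
        x <- seq_len(len)
        # forward starts: s in [x - L + 1, x] and s in [1, len - k + 1]
        flo <- pmax(x - L + 1L, 1L)
        fhi <- pmin(x, len - k + 1L)
        nf <- pmax(fhi - flo + 1L, 0L)
        sf <- ifelse(nf > 0L, cm[fhi + 1L] - cm[flo], 0)
        # reverse starts: s in [x, x + L - 1] and s in [k, len];
        # score(s) = M[s - k + 1]
        rlo <- pmax(x, k)
        rhi <- pmin(x + L - 1L, len)
        nr <- pmax(rhi - rlo + 1L, 0L)
        sr <- ifelse(nr > 0L, cm[rhi - k + 2L] - cm[rlo - k + 1L], 0)
        tot <- nf + nr
        ifelse(tot > 0L, (sf + sr) / tot, 0)
    })
    new("MappabilityTrack", scores = scores, definition = track@definition,
        k = k, extended = TRUE, fragLength = L)
}

.binTiling <- function(seqlens, binSize) {
    binSize <- as.integer(binSize)
    stopifnot(binSize >= 1L)
    grl <- lapply(names(seqlens), function(ch) {
        st <- seq.int(1L, seqlens[[ch]], by = binSize)
        GenomicRanges::GRanges(ch, IRanges::IRanges(
            st, end = pmin(st + binSize - 1L, seqlens[[ch]])))
    })
    gr <- do.call(c, grl)
    GenomeInfoDb::seqlengths(gr) <- seqlens[GenomeInfoDb::seqlevels(gr)]
    gr
}

#' @export
setGeneric("binScores", function(x, binSize, ...) standardGeneric("binScores"))

#' Bin-level mean mappability
#'
#' Averages per-position mappability scores over non-overlapping tiling
#' bins.
#'
#' @param x a \code{MappabilityTrack} or a \code{DNAStringSet} (for GC
#'   content; see below).
#' @param binSize bin width in bp.
#' @param ... unused.
#' @return \code{GRanges} tiling with a \code{score} metadata column.
#' @export
setMethod("binScores", "MappabilityTrack", function(x, binSize, ...) {
    seqlens <- vapply(x@scores, length, 0L)
    bins <- .binTiling(seqlens, binSize)
    sc <- numeric(length(bins))
    off <- 0L
    for (ch in names(x@scores)) {
        M <- x@scores[[ch]]
        cm <- c(0, cumsum(M))
        sel <- which(as.character(GenomicRanges::seqnames(bins)) == ch)
        st <- GenomicRanges::start(bins)[sel]
        en <- GenomicRanges::end(bins)[sel]
        sc[sel] <- (cm[en + 1L] - cm[st]) / (en - st + 1L)
    }
    S4Vectors::mcols(bins)$score <- sc
    bins
})

#' Bin-level GC content
#'
#' GC content of a bin is the fraction of G/C among its non-N bases; bins
#' consisting only of the ambiguous base N are excluded from the tiling.
#'
#' @param x a \code{DNAStringSet} genome.
#' @param binSize bin width in bp.
#' @param ... unused.
#' @return \code{GRanges} tiling (all-N bins dropped) with a \code{score}
#'   metadata column holding the GC fraction.
#' @export
setMethod("binScores", "DNAStringSet", function(x, binSize, ...) {
    seqlens <- .seqlens(x)
    bins <- .binTiling(seqlens, binSize)
    gc <- numeric(length(bins))
    nn <- integer(length(bins))
    for (ch in names(x)) {
        sel <- which(as.character(GenomicRanges::seqnames(bins)) == ch)
        v <- Biostrings::Views(x[[ch]],
            start = GenomicRanges::start(bins)[sel],
            end = GenomicRanges::end(bins)[sel])
        freq <- Biostrings::letterFrequency(v, c("GC", "N"))
        wid <- GenomicRanges::width(bins)[sel]
        nonN <- wid - freq[, "N"]
        gc[sel] <- ifelse(nonN > 0L, freq[, "G|C"] / nonN, NA_real_)
        nn[sel] <- freq[, "N"]
    }
    keep <- nn < GenomicRanges::width(bins)   # drop all-N bins
    bins <- bins[keep]
    S4Vectors::mcols(bins)$score <- gc[keep]
    bins
})
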