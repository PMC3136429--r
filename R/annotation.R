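#' Annotate peaks against promoters, genic windows and duplications
#'
#' Each peak receives exactly one category, with precedence
#' PromDup > Prom > GenicDup > Genic > Dup > None.  The promoter of a gene
#' is the window of \code{promoterHalfwidth} bp either side of its TSS
#' (strand-aware); the genic window runs from \code{genicUp} bp upstream of
#' the TSS to \code{genicDown} bp downstream of the TES.  The "Dup" flavor
#' of a category applies when the peak is tied to a segmental duplication:
#' its gene resides in one, or the peak itself overlaps one.  With an empty
#' duplication set the categories collapse exactly to Prom/Genic/None.
#'
#' @param peaks \code{GRanges}.
#' @param genes \code{GRanges} of gene bodies with strand (TSS = 5' end).
#' @param segdups \code{GRanges} of segmental duplications (may be empty).
#' @param promoterHalfwidth promoter half-width in bp (default 2000; the
#'   appropriate value depends on the annotation used and should be set
#'   deliberately).
#' @param genicUp,genicDown genic window extensions in bp (defaults 10000
#'   upstream of TSS, 1000 downstream of TES).
#' @return factor of categories (levels PromDup, Prom, GenicDup, Genic,
#'   Dup, None), one per peak, with a \code{table} of category percentages
#'   attached as \code{attr(, "summary")}.
#' @export
annotatePeaks <- function(peaks, genes, segdups = GenomicRanges::GRanges(),
                          promoterHalfwidth = 2000L, genicUp = 10000L,
                          genicDown = 1000L) {
    minus <- as.character(GenomicRanges::strand(genes)) == "-"
    tss <- ifelse(minus, GenomicRanges::end(genes),
                  GenomicRanges::start(genes))
    prom <- GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
        IRanges::IRanges(pmax(tss - promoterHalfwidth, 1L),
                         tss + promoterHalfwidth))
    genic <- GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
        IRanges::IRanges(
            pmax(ifelse(minus, GenomicRanges::start(genes) - genicDown,
                        GenomicRanges::start(genes) - genicUp), 1L),
            ifelse(minus, GenomicRanges::end(genes) + genicUp,
                   GenomicRanges::end(genes) + genicDown)))
    geneInDup <- GenomicRanges::countOverlaps(genes, segdups) > 0L
    ovAny <- function(x, y) GenomicRanges::countOverlaps(x, y) > 0L
    inProm <- ovAny(peaks, prom)
    inPromDupGene <- ovAny(peaks, prom[geneInDup])
    inGenic <- ovAny(peaks, genic)
    inGenicDupGene <- ovAny(peaks, genic[geneInDup])
    inDup <- ovAny(peaks, segdups)
    cat <- rep("None", length(peaks))
    cat[inDup] <- "Dup"
    cat[inGenic & !(inGenicDupGene | inDup)] <- "Genic"
    cat[inGenic & (inGenicDupGene | inDup)] <- "GenicDup"
    cat[inProm & !(inPromDupGene | inDup)] <- "Prom"
    cat[inProm & (inPromDupGene | inDup)] <- "PromDup"
    out <- factor(cat, levels = c("PromDup", "Prom", "GenicDup", "Genic",
                                  "Dup", "None"))
    attr(out, "summary") <- round(100 * table(out) / max(length(out), 1L), 2)
    out
}

.checkIupac <- function(pattern) {
    ok <- strsplit(pattern, "")[[1]] %in%
        names(Biostrings::IUPAC_CODE_MAP)
    if (!all(ok))
        stop("invalid IUPAC symbol(s) in pattern: ",
             paste(unique(strsplit(pattern, "")[[1]][!ok]), collapse = ", "))
    invisible(TRUE)
}

.peakSeqs <- function(peaks, genome) {
    out <- character(length(peaks))
    for (ch in unique(as.character(GenomicRanges::seqnames(peaks)))) {
        sel <- as.character(GenomicRanges::seqnames(peaks)) == ch
        out[sel] <- as.character(Biostrings::extractAt(genome[[ch]],
            IRanges::IRanges(GenomicRanges::start(peaks)[sel],
                             GenomicRanges::end(peaks)[sel])))
    }
    Biostrings::DNAStringSet(out)
}

#' Count consensus-motif occurrences in peak regions
#'
#' Scans both strands of every peak sequence for an IUPAC consensus pattern
#' (e.g. \code{"WGATAR"} for the GATA consensus [A/T]GATA[A/G]); overlapping
#' matches are counted.
#'
#' @param peaks \code{GRanges}.
#' @param genome \code{DNAStringSet}.
#' @param pattern IUPAC consensus string.
#' @return list with \code{counts} (per-peak occurrence counts, both
#'   strands) and \code{proportion} (fraction of peaks with at least one
#'   occurrence).
#' @export
countConsensus <- function(peaks, genome, pattern) {
    .checkIupac(pattern)
    seqs <- .peakSeqs(peaks, genome)
    pat <- Biostrings::DNAString(pattern)
    cnt <- Biostrings::vcountPattern(pat, seqs, fixed = FALSE) +
        Biostrings::vcountPattern(Biostrings::reverseComplement(pat), seqs,
                                  fixed = FALSE)
    list(counts = cnt,
         proportion = if (length(cnt)) mean(cnt >= 1L) else NA_real_)
}

#' Matched-null motif enrichment test
#'
#' Builds an empirical null for the proportion of peaks containing a motif:
#' for each replicate, every peak is replaced by a random region from the
#' same chromosome with exactly the peak's width and with mean mappability
#' and GC content within the matching tolerances; the motif-occurrence
#' proportion of each of the \code{nSets} matched sets forms the null
#' distribution, and the p-value is the fraction of null sets whose
#' proportion exceeds the observed one.  Peaks are processed in a canonical
#' coordinate order so the result does not depend on the input ordering.
#'
#' @param peaks \code{GRanges}.
#' @param genome \code{DNAStringSet}.
#' @param mapTrack per-position \code{\linkS4class{MappabilityTrack}} used
#'   for the mappability matching (typically the fragment-extended track
#'   used for binning).
#' @param pattern IUPAC consensus string.
#' @param nSets number of null peak sets (default 10000).
#' @param tolMap,tolGC matching tolerances for mean mappability and GC
#'   (default 0.05 each).  If a peak has no acceptable match the tolerances
#'   are doubled, up to \code{maxWiden} times, with a warning; an unmatched
#'   peak after that is an error.
#' @param maxWiden tolerance doublings allowed (default 4).
#' @param seed integer seed.
#' @return list with \code{p_value}, \code{observed_proportion},
#'   \code{null_proportions} (length \code{nSets}) and \code{n_sets}.
#' @export
matchedNullTest <- function(peaks, genome, mapTrack, pattern,
                            nSets = 10000L, tolMap = 0.05, tolGC = 0.05,
                            maxWiden = 4L, seed = 1L) {
    .checkIupac(pattern)
    stopifnot(is(mapTrack, "MappabilityTrack"))
    peaks <- sort(GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                         GenomicRanges::ranges(peaks)))
    lens <- .seqlens(genome)
    m <- nchar(pattern)
    pat <- Biostrings::DNAString(pattern)
    # per-chromosome cumulative sums: mappability, GC, N, motif starts
    pre <- lapply(names(genome), function(ch) {
        s <- genome[[ch]]
        gc <- as.integer(strsplit(as.character(s), "")[[1]] %in% c("G", "C"))
        nn <- as.integer(strsplit(as.character(s), "")[[1]] == "N")
        occ <- integer(lens[[ch]])
        st <- c(IRanges::start(Biostrings::matchPattern(pat, s,
                                                        fixed = FALSE)),
                IRanges::start(Biostrings::matchPattern(
                    Biostrings::reverseComplement(pat), s, fixed = FALSE)))
        occ[unique(st)] <- 1L  # either-strand match starting here
        list(cm = c(0, cumsum(mapTrack@scores[[ch]])),
             cgc = c(0, cumsum(gc)), cn = c(0, cumsum(nn)),
             cocc = c(0, cumsum(occ)))
    })
    names(pre) <- names(genome)
    regionStats <- function(ch, s, wdt) {
        p <- pre[[ch]]
        e <- s + wdt - 1L
        nonN <- wdt - (p$cn[e + 1L] - p$cn[s])
        list(map = (p$cm[e + 1L] - p$cm[s]) / wdt,
             gc = ifelse(nonN > 0L, (p$cgc[e + 1L] - p$cgc[s]) / nonN, NA),
             has = (p$cocc[pmax(e - m + 2L, s)] - p$cocc[s]) > 0L)
    }
    chs <- as.character(GenomicRanges::seqnames(peaks))
    sts <- GenomicRanges::start(peaks)
    wds <- GenomicRanges::width(peaks)
    obs_has <- logical(length(peaks))
    cand <- vector("list", length(peaks))
    for (i in seq_along(peaks)) {
        ch <- chs[i]; wdt <- wds[i]
        st_all <- seq_len(lens[[ch]] - wdt + 1L)
        stats_all <- regionStats(ch, st_all, wdt)
        self <- regionStats(ch, sts[i], wdt)
        obs_has[i] <- self$has
        tm <- tolMap; tg <- tolGC
        for (tryi in 0:maxWiden) {
            ok <- !is.na(stats_all$gc) &
                abs(stats_all$map - self$map) <= tm &
                abs(stats_all$gc - self$gc) <= tg
            if (any(ok)) break
            tm <- tm * 2; tg <- tg * 2
            warning("widening matching tolerances for peak ", i)
        }
        if (!any(ok))
            stop("no matched null region for peak ", i, " (", ch, ":",
                 sts[i], "-", sts[i] + wdt - 1L, ")")
        cand[[i]] <- list(starts = st_all[ok],
                          has = stats_all$has[ok])
    }
    observed <- mean(obs_has)
    set.seed(seed)
    null_mat <- vapply(seq_along(peaks), function(i) {
        idx <- sample.int(length(cand[[i]]$starts), nSets, replace = TRUE)
        cand[[i]]$has[idx]
    }, logical(nSets))
    null_prop <- if (length(peaks) == 1L) as.numeric(null_mat) else
        rowMeans(null_mat)
    # non-strict comparison: when the motif is absent genome-wide the
    # observed and all null proportions are 0 and the p-value must be 1
    list(p_value = mean(null_prop >= observed),
         observed_proportion = observed,
         null_proportions = null_prop, n_sets = as.integer(nSets))
}

#' TSS aggregation profile
#'
#' Extracts a strand-oriented window of bins around every gene's TSS,
#' averages the chosen count column across genes, and normalizes by
#' subtracting the mean of the boundary bins (\code{normBins} bins at each
#' end; 2 by default, 4 reproduces the wider boundary-averaging variant).
#' Genes whose window exceeds the chromosome are skipped and counted.
#' When a duplication set is supplied the profile is additionally
#' stratified into genes residing in duplications versus not.
#'
#' @param bins a \code{\linkS4class{BinTable}}.
#' @param genes \code{GRanges} of gene bodies with strand.
#' @param column bin column to aggregate (default \code{"chip_count"}).
#' @param flank half-window around the TSS in bp (default 2000; must be a
#'   multiple of the bin size).
#' @param normBins boundary bins averaged at each end for the
#'   normalization (default 2).
#' @param segdups optional \code{GRanges} for stratification.
#' @return data.frame with columns \code{offset} (bp of the bin start
#'   relative to the TSS, strand-oriented), \code{mean_count} (normalized)
#'   and \code{group} (\code{"all"}, or \code{"duplicated"} /
#'   \code{"unduplicated"}); the number of skipped genes is attached as
#'   \code{attr(, "skipped")}.
#' @export
tssProfile <- function(bins, genes, column = "chip_count", flank = 2000L,
                       normBins = 2L, segdups = NULL) {
    stopifnot(is(bins, "BinTable"))
    B <- binSize(bins)
    if (flank %% B != 0L) stop("flank must be a multiple of the bin size")
    nb <- flank %/% B
    gr <- bins@bins
    vals <- S4Vectors::mcols(gr)[[column]]
    if (is.null(vals)) stop("no bin column '", column, "'")
    lens <- GenomeInfoDb::seqlengths(gr)
    # full per-chromosome bin vectors (excluded all-N bins -> NA)
    vecs <- lapply(names(lens), function(ch) {
        n <- ceiling(lens[[ch]] / B)
        v <- rep(NA_real_, n)
        sel <- as.character(GenomicRanges::seqnames(gr)) == ch
        v[(GenomicRanges::start(gr)[sel] - 1L) %/% B + 1L] <- vals[sel]
        v
    })
    names(vecs) <- names(lens)
    minus <- as.character(GenomicRanges::strand(genes)) == "-"
    tss <- ifelse(minus, GenomicRanges::end(genes),
                  GenomicRanges::start(genes))
    rows <- matrix(NA_real_, nrow = length(genes), ncol = 2L * nb)
    skipped <- 0L
    for (i in seq_along(genes)) {
        ch <- as.character(GenomicRanges::seqnames(genes)[i])
        v <- vecs[[ch]]
        t <- (tss[i] - 1L) %/% B + 1L
        lo <- t - nb; hi <- t + nb - 1L
        if (is.null(v) || lo < 1L || hi > length(v)) {
            skipped <- skipped + 1L
            next
        }
        win <- v[lo:hi]
        if (minus[i]) win <- rev(win)
        rows[i, ] <- win
    }
    offsets <- seq(-nb, nb - 1L) * B
    profileOf <- function(sel) {
        mm <- colMeans(rows[sel, , drop = FALSE], na.rm = TRUE)
        edge <- c(seq_len(normBins), 2L * nb - seq_len(normBins) + 1L)
        mm - mean(mm[edge])
    }
    used <- rowSums(!is.na(rows)) > 0L
    if (is.null(segdups)) {
        out <- data.frame(offset = offsets, mean_count = profileOf(used),
                          group = "all")
    } else {
        inDup <- GenomicRanges::countOverlaps(genes, segdups) > 0L
        out <- rbind(
            data.frame(offset = offsets,
                       mean_count = profileOf(used & inDup),
                       group = "duplicated"),
            data.frame(offset = offsets,
                       mean_count = profileOf(used & !inDup),
                       group = "unduplicated"))
    }
    attr(out, "skipped") <- skipped
    out
}
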