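#' Partition UR and MR peak sets
#'
#' Peaks from the uni-read-only (UR) and multi-read (MR) analyses are
#' partitioned into common, MR-only, UR-only and ambiguous lists.  Peaks
#' overlapping (by at least \code{minOverlap} bp) a peak of the other
#' analysis are common.  A non-overlapping MR peak is MR-only when its UR
#' read count over the peak region is below \code{threshold} (default 20),
#' making it highly unlikely that the UR analysis could ever score it;
#' otherwise it is ambiguous.  Symmetrically for UR peaks.
#'
#' @param urPeaks,mrPeaks \code{GRanges} from \code{\link{callPeaks}} on the
#'   UR and MR bin tables.
#' @param urBins,mrBins the corresponding \code{\linkS4class{BinTable}}s,
#'   used to compute the cross-sample read counts.
#' @param threshold uniqueness read-count threshold (default 20).
#' @param minOverlap minimum overlap in bp to call peaks common (default 1).
#' @return list with \code{GRanges} elements \code{common} (peaks of either
#'   analysis, with a \code{set} column), \code{mr_only}, \code{ur_only},
#'   \code{ambiguous}; the four lists partition the union of the inputs.
#' @export
comparePeakSets <- function(urPeaks, mrPeaks, urBins, mrBins,
                            threshold = 20L, minOverlap = 1L) {
    crossCount <- function(peaks, bt) {
        if (length(peaks) == 0L) return(numeric(0))
        hit <- GenomicRanges::findOverlaps(peaks, bt@bins)
        cnt <- numeric(length(peaks))
        if (length(hit)) {
            s <- rowsum(S4Vectors::mcols(bt@bins)$chip_count[
                S4Vectors::subjectHits(hit)], S4Vectors::queryHits(hit))
            cnt[as.integer(rownames(s))] <- s[, 1L]
        }
        cnt
    }
    ov <- GenomicRanges::findOverlaps(mrPeaks, urPeaks,
                                      minoverlap = minOverlap)
    mr_common <- unique(S4Vectors::queryHits(ov))
    ur_common <- unique(S4Vectors::subjectHits(ov))
    mr_rest <- setdiff(seq_along(mrPeaks), mr_common)
    ur_rest <- setdiff(seq_along(urPeaks), ur_common)
    mr_urcnt <- crossCount(mrPeaks, urBins)
    ur_mrcnt <- crossCount(urPeaks, mrBins)
    mr_only <- mr_rest[mr_urcnt[mr_rest] < threshold]
    ur_only <- ur_rest[ur_mrcnt[ur_rest] < threshold]
    amb_mr <- setdiff(mr_rest, mr_only)
    amb_ur <- setdiff(ur_rest, ur_only)
    tag <- function(gr, set) {
        if (length(gr)) S4Vectors::mcols(gr)$set <- set
        gr
    }
    common <- c(tag(urPeaks[ur_common], "UR"), tag(mrPeaks[mr_common], "MR"))
    list(common = common,
         mr_only = tag(mrPeaks[mr_only], "MR"),
         ur_only = tag(urPeaks[ur_only], "UR"),
         ambiguous = c(tag(urPeaks[amb_ur], "UR"),
                       tag(mrPeaks[amb_mr], "MR")))
}

#' Collapse the weighted reads mapping to each peak
#'
#' A read belongs to a peak when its alignment interval overlaps the peak
#' region.  Multiple mappings of the same read inside one peak are collapsed
#' to a single entry with their weights summed, so each profile is a unique
#' read set with combined weights.
#'
#' @param peaks \code{GRanges} of peaks.
#' @param x a weighted \code{\linkS4class{ReadAlignments}}.
#' @return named list (one element per peak, named \code{peak<i>} or by the
#'   peaks' own names) of data.frames with columns \code{read_id},
#'   \code{weight} (combined within the peak) and \code{uni} (logical:
#'   uni-read genome-wide).
#' @export
peakReadProfiles <- function(peaks, x) {
    stopifnot(is(x, "ReadAlignments"))
    if (!isWeighted(x)) stop("alignments must be weighted")
    gr <- alignments(x)
    mc <- S4Vectors::mcols(gr)
    k <- table(mc$read_id)
    uni_ids <- names(k)[k == 1L]
    hit <- GenomicRanges::findOverlaps(peaks, gr)
    nms <- if (!is.null(names(peaks)) && all(nzchar(names(peaks))))
        names(peaks) else sprintf("peak%d", seq_along(peaks))
    out <- rep(list(data.frame(read_id = character(), weight = numeric(),
                               uni = logical())), length(peaks))
    names(out) <- nms
    if (length(hit)) {
        qi <- S4Vectors::queryHits(hit); si <- S4Vectors::subjectHits(hit)
        for (i in unique(qi)) {
            sel <- si[qi == i]
            w <- rowsum(mc$weight[sel], mc$read_id[sel])
            out[[i]] <- data.frame(read_id = rownames(w),
                                   weight = unname(w[, 1L]),
                                   uni = rownames(w) %in% uni_ids,
                                   stringsAsFactors = FALSE)
        }
    }
    out
}

#' Multi-read similarity between two peak read profiles
#'
#' Each read shared by the two peaks contributes \eqn{1 - |w_i - w_j|},
#' where \eqn{w_i} and \eqn{w_j} are its combined weights in the two peaks:
#' a read allocated 0.9/0.1 makes the peaks more different than one
#' allocated 0.6/0.4.  Consequently the self-similarity of a peak equals its
#' total read count, and if every shared read is weighted 0.5 in both peaks
#' the similarity equals the number of overlapping reads.  The normalized
#' score divides by the larger of the two peaks' read counts, giving a value
#' in [0, 1] comparable across peaks.  Whether the shared reads' weights
#' differ systematically between the peaks is assessed with a paired t-test
#' and a Wilcoxon signed-rank test (NA with fewer than 2 shared reads or
#' degenerate differences).
#'
#' @param profile_i,profile_j profiles from \code{\link{peakReadProfiles}}
#'   built from the same weight set.
#' @return one-row data.frame: \code{n_shared}, \code{similarity}
#'   (unnormalized), \code{similarity_normalized}, \code{t_pvalue},
#'   \code{wilcoxon_pvalue}.
#' @export
peakSimilarity <- function(profile_i, profile_j) {
    shared <- intersect(profile_i$read_id, profile_j$read_id)
    wi <- profile_i$weight[match(shared, profile_i$read_id)]
    wj <- profile_j$weight[match(shared, profile_j$read_id)]
    s <- sum(1 - abs(wi - wj))
    nmax <- max(nrow(profile_i), nrow(profile_j))
    tp <- wp <- NA_real_
    if (length(shared) >= 2L) {
        tp <- tryCatch(t.test(wi, wj, paired = TRUE)$p.value,
                       error = function(e) NA_real_)
        wp <- tryCatch(suppressWarnings(
            wilcox.test(wi, wj, paired = TRUE)$p.value),
            error = function(e) NA_real_)
    }
    data.frame(n_shared = length(shared), similarity = s,
               similarity_normalized = if (nmax > 0) s / nmax else 0,
               t_pvalue = tp, wilcoxon_pvalue = wp)
}

#' All-pairs similarity records
#'
#' @param profiles list from \code{\link{peakReadProfiles}}.
#' @return data.frame with columns \code{i}, \code{j} (profile names) and
#'   the \code{\link{peakSimilarity}} fields, one row per unordered pair
#'   sharing at least one read.
#' @export
similarityMatrix <- function(profiles) {
    nms <- names(profiles)
    out <- list(); n <- 0L
    for (a in seq_along(profiles)) {
        ids_a <- profiles[[a]]$read_id
        if (!length(ids_a)) next
        for (b in seq_along(profiles)) {
            if (b <= a) next
            if (!any(ids_a %in% profiles[[b]]$read_id)) next
            rec <- peakSimilarity(profiles[[a]], profiles[[b]])
            n <- n + 1L
            out[[n]] <- cbind(data.frame(i = nms[a], j = nms[b],
                                         stringsAsFactors = FALSE), rec)
        }
    }
    if (n == 0L)
        return(data.frame(i = character(), j = character(),
                          n_shared = integer(), similarity = numeric(),
                          similarity_normalized = numeric(),
                          t_pvalue = numeric(), wilcoxon_pvalue = numeric()))
    do.call(rbind, out)
}

#' Classify MR-only peaks by their shared multi-reads
#'
#' MR-only peaks are screened for double counting: a peak sharing no
#' multi-read with any other peak is Type-III.  Otherwise it is evaluated
#' against its maximum-similarity partner and labeled Type-II when it has
#' independent support: (a) the sum of its multi-read allocation weights
#' from reads not shared with the partner is at least
#' \code{thresholds$mass}; or (b) it has at least \code{thresholds$unireads}
#' uni-reads; or (c) the ratio of unshared to shared multi-read fractional
#' counts is at least \code{thresholds$ratio}.  Peaks failing all three are
#' Type-I: candidates for segmental-duplication artifacts whose signal is
#' largely the mirror of another peak's.
#'
#' @param profiles profile list for all MR peaks (the candidate partners),
#'   from \code{\link{peakReadProfiles}}.
#' @param mrOnly names (or indices) of the MR-only peaks within
#'   \code{profiles}.
#' @param thresholds list with \code{mass} (default 20), \code{unireads}
#'   (20) and \code{ratio} (2).
#' @param partnerMode \code{"max"} evaluates criteria against the
#'   maximum-similarity partner (default); \code{"any"} labels Type-II if
#'   the criteria hold against every sharing partner.
#' @return data.frame with one row per MR-only peak: \code{peak},
#'   \code{type} (\code{"Type-I"}, \code{"Type-II"}, \code{"Type-III"}),
#'   \code{criterion} (\code{"a"}, \code{"b"}, \code{"c"} or \code{"none"}),
#'   \code{partner}, \code{n_shared}, \code{similarity_normalized}.
#' @export
classifyMROnly <- function(profiles, mrOnly,
                           thresholds = list(mass = 20, unireads = 20,
                                             ratio = 2),
                           partnerMode = c("max", "any")) {
    partnerMode <- match.arg(partnerMode)
    nms <- names(profiles)
    if (is.numeric(mrOnly)) mrOnly <- nms[mrOnly]
    evalCrit <- function(pi, pj) {
        shared <- intersect(pi$read_id, pj$read_id)
        multi <- !pi$uni
        sh <- pi$read_id %in% shared
        unshared_mass <- sum(pi$weight[multi & !sh])
        shared_mass <- sum(pi$weight[multi & sh])
        n_uni <- sum(pi$uni)
        if (unshared_mass >= thresholds$mass) "a"
        else if (n_uni >= thresholds$unireads) "b"
        else if (shared_mass > 0 &&
                 unshared_mass / shared_mass >= thresholds$ratio) "c"
        else "none"
    }
    rows <- lapply(mrOnly, function(nm) {
        pi <- profiles[[nm]]
        others <- setdiff(nms, nm)
        sharing <- others[vapply(others, function(o)
            any(pi$read_id[!pi$uni] %in% profiles[[o]]$read_id), FALSE)]
        if (!length(sharing))
            return(data.frame(peak = nm, type = "Type-III",
                              criterion = "none", partner = NA_character_,
                              n_shared = 0L,
                              similarity_normalized = NA_real_,
                              stringsAsFactors = FALSE))
        recs <- do.call(rbind, lapply(sharing, function(o)
            cbind(partner = o, peakSimilarity(pi, profiles[[o]]))))
        if (partnerMode == "max") {
            best <- recs[which.max(recs$similarity_normalized), ]
            crit <- evalCrit(pi, profiles[[best$partner]])
            data.frame(peak = nm,
                       type = if (crit == "none") "Type-I" else "Type-II",
                       criterion = crit, partner = best$partner,
                       n_shared = best$n_shared,
                       similarity_normalized = best$similarity_normalized,
                       stringsAsFactors = FALSE)
        } else {
            crits <- vapply(sharing, function(o)
                evalCrit(pi, profiles[[o]]), "")
            best <- recs[which.max(recs$similarity_normalized), ]
            allpass <- all(crits != "none")
            data.frame(peak = nm,
                       type = if (allpass) "Type-II" else "Type-I",
                       criterion = if (allpass) crits[1L] else "none",
                       partner = best$partner, n_shared = best$n_shared,
                       similarity_normalized = best$similarity_normalized,
                       stringsAsFactors = FALSE)
        }
    })
    do.call(rbind, rows)
}

#' Saturation analysis: peak recovery at reduced sequencing depth
#'
#' Gold-standard peaks are taken from the full dataset; nested subsamples of
#' the uni-read and multi-read pools are drawn at each fraction (a sample at
#' a higher fraction is a superset of every lower one), the full pipeline
#' (allocation, binning, peak calling) is re-run per subsample in UR mode
#' (sampled uni-reads only) and MR mode (sampled uni-reads plus allocated
#' sampled multi-reads), and the percentage of gold peaks overlapped by the
#' called peaks is reported.
#'
#' @param chipAln unweighted \code{ReadAlignments} for the ChIP sample.
#' @param inputAln weighted (or uni-only) \code{ReadAlignments} for the
#'   input sample; used at full depth throughout.
#' @param genome \code{DNAStringSet}.
#' @param goldPeaks \code{GRanges} of gold-standard peaks called on the
#'   full data.
#' @param fractions increasing sampling fractions in (0, 1]
#'   (default 0.2-1.0).
#' @param mapBins,gcBins precomputed covariate bins (from
#'   \code{\link{binScores}}); computed from the genome when NULL.
#' @param binSize,fragLength,w,iterations,fdr,minChipCount pipeline
#'   parameters (see the respective functions).
#' @param method peak caller: \code{"cb"} (default) or \code{"nbmix"}.
#' @param seed integer seed for the subsampling permutations.
#' @return data.frame with columns \code{fraction}, \code{ur_recovery},
#'   \code{mr_recovery} (percent of gold peaks recovered); the nested read
#'   id samples are attached as \code{attr(, "samples")}.
#' @export
saturationAnalysis <- function(chipAln, inputAln, genome, goldPeaks,
                               fractions = c(0.2, 0.4, 0.6, 0.8, 1.0),
                               mapBins = NULL, gcBins = NULL,
                               binSize = 200L, fragLength = 200L,
                               w = 100L, iterations = 200L, fdr = 0.05,
                               minChipCount = 30L,
                               method = c("cb", "nbmix"), seed = 1L) {
    method <- match.arg(method)
    if (any(fractions <= 0 | fractions > 1))
        stop("fractions must lie in (0, 1]")
    fractions <- sort(fractions)
    gr <- alignments(chipAln)
    mc <- S4Vectors::mcols(gr)
    k <- table(mc$read_id)
    uni_ids <- names(k)[k == 1L]
    multi_ids <- names(k)[k > 1L]
    set.seed(seed)
    uni_perm <- sample(uni_ids)
    multi_perm <- sample(multi_ids)
    if (is.null(gcBins)) gcBins <- binScores(genome, binSize)
    if (is.null(mapBins)) {
        occ <- kmerOccurrences(genome, chipAln@readLength)
        tr <- fragmentExtendMappability(
            nucleotideMappability(occ, "def2", k = chipAln@readLength),
            fragLength)
        mapBins <- binScores(tr, binSize)
    }
    if (!isWeighted(inputAln))
        inputAln <- allocateMultiReads(inputAln, w = w,
                                       iterations = iterations,
                                       fragLength = fragLength)
    inBins <- extendAndBin(inputAln, genome, binSize, fragLength, "MR")
    subAln <- function(ids) {
        sel <- mc$read_id %in% ids
        initialize(chipAln, alignments = gr[sel], weighted = FALSE)
    }
    recover <- function(peaks) {
        if (length(goldPeaks) == 0L) return(NA_real_)
        100 * mean(GenomicRanges::countOverlaps(goldPeaks, peaks) > 0L)
    }
    samples <- list()
    res <- lapply(fractions, function(f) {
        ids_u <- uni_perm[seq_len(floor(f * length(uni_perm)))]
        ids_m <- multi_perm[seq_len(floor(f * length(multi_perm)))]
        samples[[sprintf("%g", f)]] <<- list(uni = ids_u, multi = ids_m)
        callOn <- function(ids, mode) {
            a <- allocateMultiReads(subAln(ids), w = w,
                                    iterations = iterations,
                                    fragLength = fragLength)
            cb <- extendAndBin(a, genome, binSize, fragLength, mode)
            bt <- assembleBinTable(cb, inBins, mapBins, gcBins)
            sc <- if (method == "cb") cbTest(bt) else fitNBMixture(bt)
            callPeaks(sc, bt, fdr = fdr, minChipCount = minChipCount)
        }
        urp <- callOn(ids_u, "UR")
        mrp <- callOn(c(ids_u, ids_m), "MR")
        data.frame(fraction = f, ur_recovery = recover(urp),
                   mr_recovery = recover(mrp))
    })
    out <- do.call(rbind, res)
    attr(out, "samples") <- samples
    out
}
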