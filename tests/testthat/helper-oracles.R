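# Independent brute-force oracles and fixture builders shared by the tests.
# These deliberately avoid the package's own data structures and algorithms.

# Build a ReadAlignments object directly from a data.frame with columns
# read_id, chrom, start, width, strand, mismatches and optionally weight.
makeAlignments <- function(df, weighted = FALSE, readLength = NULL) {
    gr <- GenomicRanges::GRanges(df$chrom,
        IRanges::IRanges(start = df$start, width = df$width),
        strand = df$strand)
    S4Vectors::mcols(gr)$read_id <- df$read_id
    S4Vectors::mcols(gr)$mismatches <-
        if (!is.null(df$mismatches)) as.integer(df$mismatches) else 0L
    S4Vectors::mcols(gr)$weight <-
        if (!is.null(df$weight)) df$weight else rep(NA_real_, nrow(df))
    new("ReadAlignments", alignments = gr,
        readLength = if (is.null(readLength)) as.integer(df$width[1]) else
            as.integer(readLength),
        weighted = weighted)
}

alnDf <- function(x) {
    gr <- alignments(x)
    data.frame(read_id = S4Vectors::mcols(gr)$read_id,
               chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),
               width = GenomicRanges::width(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               mismatches = S4Vectors::mcols(gr)$mismatches,
               weight = S4Vectors::mcols(gr)$weight,
               stringsAsFactors = FALSE)
}

# Naive window sum: direct summation over a position->count table.
naiveWindowSum <- function(tab, chrom, p, w) {
    sel <- tab$chrom == chrom & tab$pos >= p - w & tab$pos <= p + w
    sum(tab$count[sel])
}

# Naive synchronous reallocation over a data.frame of alignments
# (read_id, chrom, pos), no index structure at all.
naiveAllocate <- function(df, w, iterations) {
    reads <- split(seq_len(nrow(df)), df$read_id)
    weight <- numeric(nrow(df))
    for (idx in reads) weight[idx] <- 1 / length(idx)
    for (it in seq_len(iterations)) {
        neww <- weight
        for (i in seq_along(reads)) {
            idx <- reads[[i]]
            if (length(idx) == 1L) { neww[idx] <- 1; next }
            s <- vapply(idx, function(a) {
                sel <- df$chrom == df$chrom[a] &
                    abs(df$pos - df$pos[a]) <= w
                sum(weight[sel])
            }, 0)
            neww[idx] <- if (sum(s) > 0) s / sum(s) else
                rep(1 / length(idx), length(idx))
        }
        weight <- neww
    }
    weight
}

# Brute-force k-mer occurrence counts over both strands.
bruteKmerOcc <- function(genome, k) {
    seqs <- lapply(names(genome), function(ch) as.character(genome[[ch]]))
    names(seqs) <- names(genome)
    allk <- unlist(lapply(seqs, function(s) {
        len <- nchar(s)
        if (len < k) character() else substring(s, 1:(len - k + 1), k:len)
    }))
    rc <- function(x) chartr("ACGT", "TGCA",
                             vapply(x, function(v) paste(rev(strsplit(
                                 v, "")[[1]]), collapse = ""), ""))
    lapply(seqs, function(s) {
        len <- nchar(s)
        out <- integer(len)
        if (len >= k) {
            km <- substring(s, 1:(len - k + 1), k:len)
            good <- !grepl("[^ACGT]", km)
            cnt <- integer(length(km))
            cnt[good] <- vapply(km[good], function(x)
                sum(allk == x) + sum(allk == rc(x)), 0L)
            out[seq_along(km)] <- cnt
        }
        out
    })
}

# Naive fragment-extended mappability by explicit averaging loops.
naiveExtend <- function(M, k, L) {
    len <- length(M)
    vapply(seq_len(len), function(x) {
        fs <- max(1, x - L + 1):x
        fs <- fs[fs <= len - k + 1]
        rs <- x:min(x + L - 1, len)
        rs <- rs[rs >= k]
        vals <- c(M[fs], M[rs - k + 1])
        if (length(vals)) mean(vals) else 0
    }, 0)
}

# Brute-force read mapper: scan every position on both strands.
bruteMap <- function(reads, genome, maxMismatches = 0L) {
    rc1 <- function(x) chartr("ACGT", "TGCA",
                              paste(rev(strsplit(x, "")[[1]]), collapse = ""))
    out <- list(); n <- 0L
    for (i in seq_along(reads)) {
        r <- as.character(reads[[i]])
        k <- nchar(r)
        rchars <- strsplit(r, "")[[1]]
        rrev <- strsplit(rc1(r), "")[[1]]
        for (ch in names(genome)) {
            s <- strsplit(as.character(genome[[ch]]), "")[[1]]
            for (p in seq_len(length(s) - k + 1)) {
                win <- s[p:(p + k - 1)]
                mmf <- sum(win != rchars)
                mmr <- sum(win != rrev)
                if (mmf <= maxMismatches) {
                    n <- n + 1L
                    out[[n]] <- data.frame(read_id = names(reads)[i],
                                           chrom = ch, start = p,
                                           strand = "+", mismatches = mmf)
                }
                if (mmr <= maxMismatches) {
                    n <- n + 1L
                    out[[n]] <- data.frame(read_id = names(reads)[i],
                                           chrom = ch, start = p,
                                           strand = "-", mismatches = mmr)
                }
            }
        }
    }
    if (n == 0L) return(data.frame(read_id = character(), chrom = character(),
                                   start = integer(), strand = character(),
                                   mismatches = integer()))
    do.call(rbind, out)
}

# Build a BinTable directly from vectors (peak-caller unit tests).
makeBinTable <- function(chip, input, mappability = NULL, gc = NULL,
                         binSize = 200L, chrom = "chr1") {
    n <- length(chip)
    st <- seq(1L, by = binSize, length.out = n)
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(st, width = binSize))
    GenomeInfoDb::seqlengths(gr) <- setNames(st[n] + binSize - 1L, chrom)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        chip_fractional = as.numeric(chip),
        chip_count = as.integer(chip),
        input_count = as.integer(input),
        mappability = if (is.null(mappability)) rep(1, n) else mappability,
        gc = if (is.null(gc)) runif(n, 0.3, 0.7) else gc)
    new("BinTable", bins = gr, binSize = as.integer(binSize),
        rounding = "round")
}

# Standard end-to-end fixture: genome with an exact duplicated block and
# planted peaks inside and outside the duplication.
standardFixture <- function(seed = 11L, genomeLen = 60000L,
                            dupStart = 8001L, dupWidth = 8000L,
                            dupTarget = 42001L,
                            nUnique = 3L, nDup = 2L,
                            rate = 20, depth = 9000L, k = 36L, L = 200L) {
    g <- simulateGenome(c(chr1 = genomeLen), duplications = data.frame(
        chrom = "chr1", start = dupStart, width = dupWidth,
        target_chrom = "chr1", target_start = dupTarget, identity = 1.0),
        seed = seed)
    gapLo <- dupStart + dupWidth + 1500L
    gapHi <- dupTarget - 1800L
    uniq_pos <- round(seq(gapLo, gapHi, length.out = nUnique))
    dup_pos <- round(seq(dupStart + 1500, dupStart + dupWidth - 1800,
                         length.out = nDup))
    pk <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(uniq_pos, dup_pos), width = 300L))
    S4Vectors::mcols(pk)$rate <- rate
    S4Vectors::mcols(pk)$in_dup <- rep(c(FALSE, TRUE), c(nUnique, nDup))
    sim <- simulateChipSeq(g$genome, pk, depth = depth, readLength = k,
                           fragLength = L, seed = seed + 1L)
    list(genome = g$genome, segdups = g$segdups, peaks = pk, sim = sim,
         k = k, L = L)
}

# Run the binning + covariate assembly for a weighted sample.
buildBinTable <- function(chipW, inputW, genome, k, L = 200L,
                          binSize = 200L, mode = "MR", rounding = "round",
                          mapBins = NULL, gcBins = NULL) {
    if (is.null(gcBins)) gcBins <- binScores(genome, binSize)
    if (is.null(mapBins)) {
        tr <- fragmentExtendMappability(
            nucleotideMappability(kmerOccurrences(genome, k), "def2", k = k),
            L)
        mapBins <- binScores(tr, binSize)
    }
    assembleBinTable(
        extendAndBin(chipW, genome, binSize, L, mode, rounding),
        extendAndBin(inputW, genome, binSize, L, "MR", rounding),
        mapBins, gcBins)
}
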