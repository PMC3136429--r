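writeSam <- function(records, path, chromLen = 10000L) {
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:chr1\tLN:%d", chromLen))
    writeLines(c(header, records), path)
}

samRecord <- function(qname, pos, seq = strrep("A", 10), flag = 0L,
                      nm = 0L) {
    sprintf("%s\t%d\tchr1\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
            qname, flag, pos, nchar(seq), seq, nm)
}

test_that("SAM records are grouped by read id and filtered", {
    f <- tempfile(fileext = ".sam")
    writeSam(c(samRecord("r1", 100), samRecord("r1", 500, flag = 256L),
               samRecord("r2", 900)), f)
    x <- readAlignmentFile(f)
    df <- alnDf(x)
    expect_equal(sum(df$read_id == "r1"), 2L)
    expect_equal(sum(df$read_id == "r2"), 1L)
    sm <- S4Vectors::metadata(alignments(x))$filter_summary
    expect_equal(sm$uni_reads, 1L)
    expect_equal(sm$multi_reads, 1L)
})

test_that("reads at or above the multi-hit cap are dropped", {
    f <- tempfile(fileext = ".sam")
    recs <- vapply(seq_len(100), function(i)
        samRecord("rbig", i * 50L, flag = if (i == 1) 0L else 256L), "")
    writeSam(c(recs, samRecord("rok", 6000)), f)
    x <- readAlignmentFile(f, maxHits = 100)
    df <- alnDf(x)
    expect_false("rbig" %in% df$read_id)
    expect_true("rok" %in% df$read_id)
    sm <- S4Vectors::metadata(alignments(x))$filter_summary
    expect_equal(sm$reads_dropped_max_hits, 1L)
    # 99 alignments is still kept
    f2 <- tempfile(fileext = ".sam")
    writeSam(vapply(seq_len(99), function(i)
        samRecord("r99", i * 50L, flag = if (i == 1) 0L else 256L), ""), f2)
    expect_true("r99" %in% alnDf(readAlignmentFile(f2, maxHits = 100))$read_id)
})

test_that("mismatch filtering drops alignments, then empty reads", {
    f <- tempfile(fileext = ".sam")
    writeSam(c(samRecord("r1", 100, nm = 3L), samRecord("r1", 500, nm = 1L),
               samRecord("r2", 900, nm = 3L)), f)
    x <- readAlignmentFile(f, maxMismatches = 2)
    df <- alnDf(x)
    expect_equal(nrow(df), 1L)
    expect_equal(df$start, 500L)
    expect_equal(
        S4Vectors::metadata(alignments(x))$filter_summary$reads_dropped_mismatch,
        1L)
})

test_that("empty and malformed BED-like input behave as specified", {
    f <- tempfile(fileext = ".bed")
    file.create(f)
    x <- readAlignmentFile(f, format = "bed")
    expect_equal(length(alignments(x)), 0L)
    sm <- S4Vectors::metadata(alignments(x))$filter_summary
    expect_equal(sm$reads_kept, 0L)
    expect_equal(sm$uni_reads + sm$multi_reads, 0L)
    writeLines("chr1\t100\t50\tr1\t0\t+", f)
    expect_error(readAlignmentFile(f, format = "bed"), "malformed")
})

test_that("weighted alignments round-trip exactly at 6 decimals", {
    set.seed(42)
    n_reads <- 400L
    rows <- do.call(rbind, lapply(seq_len(n_reads), function(i) {
        k <- sample(1:4, 1L)
        w <- if (k == 1L) 1 else {
            raw <- round(runif(k), 4)   # representable at 6 decimals
            raw[k] <- 1 - sum(raw[-k])
            if (any(raw < 0)) { raw <- rep(1 / k, k) }
            raw
        }
        data.frame(read_id = sprintf("r%04d", i), chrom = "chr1",
                   start = sample(1:5000, k), width = 36L,
                   strand = sample(c("+", "-"), k, replace = TRUE),
                   mismatches = 0L, weight = w)
    }))
    x <- makeAlignments(rows, weighted = TRUE)
    f <- tempfile()
    writeWeightedAlignments(x, f)
    y <- readWeightedAlignments(f)
    a <- alnDf(x); b <- alnDf(y)
    key <- function(d) order(d$read_id, d$chrom, d$start)
    a <- a[key(a), ]; b <- b[key(b), ]
    expect_equal(b$chrom, a$chrom)
    expect_equal(b$start, a$start)
    expect_equal(b$strand, a$strand)
    expect_equal(b$weight, a$weight, tolerance = 1e-6)
})

test_that("pseudo-read export keeps the argmax location above 0.5", {
    df <- rbind(
        data.frame(read_id = "m1", chrom = "chr1", start = c(100L, 900L),
                   width = 36L, strand = "+", mismatches = 0L,
                   weight = c(0.9, 0.1)),
        data.frame(read_id = "m2", chrom = "chr1",
                   start = c(100L, 500L, 900L), width = 36L, strand = "+",
                   mismatches = 0L, weight = c(0.3, 0.3, 0.4)),
        data.frame(read_id = "m3", chrom = "chr1", start = c(200L, 700L),
                   width = 36L, strand = "+", mismatches = 0L,
                   weight = c(0.5, 0.5)),
        data.frame(read_id = "u1", chrom = "chr1", start = 1500L,
                   width = 36L, strand = "-", mismatches = 0L, weight = 1))
    x <- makeAlignments(df, weighted = TRUE)
    out <- exportPseudoReads(x)
    ids <- S4Vectors::mcols(out)$read_id
    expect_setequal(ids, c("m1", "m3", "u1"))
    expect_equal(GenomicRanges::start(out)[ids == "m1"], 100L)
    expect_equal(GenomicRanges::start(out)[ids == "m3"], 200L)  # tie: smaller
    expect_equal(GenomicRanges::start(out)[ids == "u1"], 1500L)
})

test_that("pseudo-read export equals a brute-force argmax pass", {
    set.seed(7)
    rows <- do.call(rbind, lapply(1:300, function(i) {
        k <- sample(1:4, 1L)
        w <- as.numeric(rmultinom(1, 20, rep(1, k))) / 20
        data.frame(read_id = sprintf("r%03d", i),
                   chrom = sample(c("chr1", "chr2"), k, replace = TRUE),
                   start = sample(1:5000, k), width = 36L, strand = "+",
                   mismatches = 0L, weight = w)
    }))
    x <- makeAlignments(rows, weighted = TRUE)
    out <- exportPseudoReads(x)
    got <- data.frame(read_id = S4Vectors::mcols(out)$read_id,
                      chrom = as.character(GenomicRanges::seqnames(out)),
                      start = GenomicRanges::start(out))
    want <- do.call(rbind, lapply(split(rows, rows$read_id), function(d) {
        mx <- max(d$weight)
        if (mx < 0.5) return(NULL)
        cand <- d[d$weight == mx, ]
        cand <- cand[order(cand$chrom, cand$start), ][1L, ]
        cand[, c("read_id", "chrom", "start")]
    }))
    got <- got[order(got$read_id), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want[order(want$read_id), ])
})

test_that("interval files round-trip and reject bad coordinates", {
    gr <- GenomicRanges::GRanges(
        sample(c("chr1", "chr2"), 100, replace = TRUE),
        IRanges::IRanges(start = sample(1:10000, 100), width = 50:149))
    S4Vectors::mcols(gr)$label <- sprintf("iv%03d", 1:100)
    f <- tempfile(fileext = ".bed")
    writeIntervals(gr, f)
    back <- readIntervals(f)
    expect_equal(as.character(GenomicRanges::seqnames(back)),
                 as.character(GenomicRanges::seqnames(gr)))
    expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
    expect_equal(GenomicRanges::width(back), GenomicRanges::width(gr))
    expect_equal(S4Vectors::mcols(back)$label, S4Vectors::mcols(gr)$label)
    f2 <- tempfile(fileext = ".bed")
    writeLines("chr1\t100\t50\tbad", f2)
    expect_error(readIntervals(f2), "inverted")
    writeLines("chr1\t-5\t50\tbad", f2)
    expect_error(readIntervals(f2), "negative")
    writeLines("chr1\t0\t100\tdup", f2)
    one <- readIntervals(f2)
    expect_equal(GenomicRanges::width(one), 100L)
    expect_equal(S4Vectors::mcols(one)$label, "dup")
})
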