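test_that("window sums match naive summation on random data", {
    set.seed(21)
    tab <- data.frame(chrom = sample(c("chr1", "chr2"), 500, replace = TRUE),
                      pos = sample(1:20000, 500, replace = TRUE),
                      count = runif(500, 0, 3))
    ci <- countIndex(tab$chrom, tab$pos, tab$count)
    for (q in seq_len(100)) {
        ch <- sample(c("chr1", "chr2"), 1)
        p <- sample(1:20000, 1)
        w <- sample(c(5L, 50L, 500L, 5000L), 1)
        expect_equal(windowSum(ci, ch, p, w), naiveWindowSum(tab, ch, p, w))
    }
    expect_equal(windowSum(countIndex(character(), integer()), "chr1",
                           100, 50) |> suppressWarnings(), 0)
    ci1 <- countIndex("chr1", 777L, 1.0)
    expect_equal(windowSum(ci1, "chr1", 777, 1), 1.0)
    expect_equal(windowSum(ci1, "chr1", 777, 10000), 1.0)
    expect_warning(windowSum(ci1, "chrX", 1, 1), "unknown")
})

test_that("incremental index updates keep window sums exact", {
    set.seed(22)
    pos <- sort(sample(1:5000, 200))
    ci <- countIndex(rep("chr1", 200), pos)
    tab <- data.frame(chrom = "chr1", pos = pos, count = 0)
    for (i in seq_len(300)) {
        j <- sample(200, 1)
        d <- runif(1, -0.2, 1)
        d <- max(d, -tab$count[j])          # counts stay nonnegative
        indexAdd(ci, "chr1", pos[j], d)
        tab$count[j] <- tab$count[j] + d
        p <- sample(1:5000, 1); w <- sample(c(10L, 100L, 1000L), 1)
        expect_equal(windowSum(ci, "chr1", p, w),
                     naiveWindowSum(tab, "chr1", p, w), tolerance = 1e-12)
    }
    expect_error(indexAdd(ci, "chr1", 4999999L, 1), "not stored")
})

test_that("uni-reads keep weight exactly 1 and multi-reads conserve mass", {
    set.seed(23)
    rows <- do.call(rbind, lapply(1:200, function(i) {
        k <- sample(c(1, 1, 2, 3, 5), 1)
        data.frame(read_id = sprintf("r%03d", i), chrom = "chr1",
                   start = sample(1:50000, k), width = 36L, strand = "+",
                   mismatches = 0L)
    }))
    x <- allocateMultiReads(makeAlignments(rows), w = 100, iterations = 30)
    df <- alnDf(x)
    k <- table(df$read_id)
    uni <- df$read_id %in% names(k)[k == 1]
    expect_true(all(df$weight[uni] == 1))
    sums <- tapply(df$weight, df$read_id, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
    expect_true(all(df$weight >= 0 & df$weight <= 1))
})

test_that("a symmetric two-site multi-read stays at 0.5/0.5", {
    df <- data.frame(read_id = "m1", chrom = "chr1",
                     start = c(1000L, 9000L), width = 36L, strand = "+",
                     mismatches = 0L)
    x <- allocateMultiReads(makeAlignments(df), w = 100, iterations = 200)
    expect_equal(alnDf(x)$weight, c(0.5, 0.5))
})

test_that("a uni-read neighbor drives the closed-form capture recursion", {
    # uni-read at p; multi-read at p+2 and at a distant q.  With f0 = 0.5
    # the favored fraction follows f' = (1 + f) / 2, so after n iterations
    # f = 1 - 2^-(n+1).
    df <- data.frame(read_id = c("u1", "m1", "m1"), chrom = "chr1",
                     start = c(5000L, 5002L, 90000L), width = 36L,
                     strand = "+", mismatches = 0L)
    for (n in c(1L, 3L, 10L)) {
        x <- allocateMultiReads(makeAlignments(df), w = 5, iterations = n)
        got <- alnDf(x)
        f <- got$weight[got$read_id == "m1" & got$start == 5002L]
        expect_equal(f, 1 - 2^-(n + 1), tolerance = 1e-12)
    }
    # monotone geometric capture
    fs <- vapply(1:8, function(n) {
        x <- allocateMultiReads(makeAlignments(df), w = 5, iterations = n)
        got <- alnDf(x)
        got$weight[got$read_id == "m1" & got$start == 5002L]
    }, 0)
    expect_true(all(diff(fs) > 0))
    expect_equal(fs, 1 - 2^-(2:9), tolerance = 1e-12)
})

test_that("the indexed allocation agrees exactly with a naive version", {
    set.seed(24)
    rows <- do.call(rbind, lapply(1:120, function(i) {
        k <- sample(c(1, 1, 1, 2, 3), 1)
        data.frame(read_id = sprintf("r%03d", i),
                   chrom = sample(c("chr1", "chr2"), 1),
                   start = sample(1:8000, k), width = 30L, strand = "+",
                   mismatches = 0L)
    }))
    x <- allocateMultiReads(makeAlignments(rows), w = 75, iterations = 12)
    got <- alnDf(x)
    naive_in <- data.frame(read_id = got$read_id, chrom = got$chrom,
                           pos = got$start)
    want <- naiveAllocate(naive_in, w = 75, iterations = 12)
    expect_equal(got$weight, want, tolerance = 1e-12)
})

test_that("final weights do not depend on the input read order", {
    set.seed(25)
    rows <- do.call(rbind, lapply(1:80, function(i) {
        k <- sample(1:3, 1)
        data.frame(read_id = sprintf("r%03d", i), chrom = "chr1",
                   start = sample(1:10000, k), width = 36L, strand = "+",
                   mismatches = 0L)
    }))
    x1 <- allocateMultiReads(makeAlignments(rows), w = 100, iterations = 15)
    rows2 <- rows[sample(nrow(rows)), ]
    x2 <- allocateMultiReads(makeAlignments(rows2), w = 100, iterations = 15)
    a <- alnDf(x1); b <- alnDf(x2)
    a <- a[order(a$read_id, a$start), ]; b <- b[order(b$read_id, b$start), ]
    expect_equal(a$weight, b$weight, tolerance = 1e-12)
})

test_that("allocation summary reports the rescued percentage", {
    rows <- rbind(
        do.call(rbind, lapply(1:100, function(i)
            data.frame(read_id = sprintf("u%03d", i), chrom = "chr1",
                       start = i * 50L, width = 36L, strand = "+",
                       mismatches = 0L))),
        do.call(rbind, lapply(1:20, function(i)
            data.frame(read_id = sprintf("m%03d", i), chrom = "chr1",
                       start = c(i * 97L, i * 97L + 20000L), width = 36L,
                       strand = "+", mismatches = 0L))))
    s <- allocationSummary(makeAlignments(rows))
    expect_equal(s$uni_reads, 100L)
    expect_equal(s$multi_reads, 20L)
    expect_equal(s$rescued_pct, 20)
    s0 <- allocationSummary(makeAlignments(rows[1:100, ]))
    expect_equal(s0$rescued_pct, 0)
    sNA <- allocationSummary(makeAlignments(rows[101:140, ]))
    expect_true(is.na(sNA$rescued_pct))
})

test_that("multi-read fraction on a duplicated genome matches the truth", {
    fx <- standardFixture(seed = 31L, genomeLen = 40000L, dupStart = 5001L,
                          dupWidth = 6000L, dupTarget = 28001L,
                          nUnique = 1L, nDup = 1L, depth = 3000L)
    aln <- exactMultiMap(fx$sim$chip, fx$genome)
    s <- allocationSummary(aln)
    # reads whose full tag lies inside a duplicated block are ambiguous
    orig <- fx$sim$truth$chip_origins
    st <- ifelse(orig$strand == "+", orig$frag_start,
                 orig$frag_start + fx$L - fx$k)
    in_dup <- (st >= 5001 & st + fx$k - 1 <= 11000) |
              (st >= 28001 & st + fx$k - 1 <= 34000)
    p_true <- mean(in_dup)
    p_obs <- s$multi_reads / (s$uni_reads + s$multi_reads)
    sigma <- sqrt(p_true * (1 - p_true) / 3000)
    expect_lt(abs(p_obs - p_true), 3 * sigma + 2e-3)
})
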