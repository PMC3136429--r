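mkPeaks <- function(starts, width = 400L) {
    GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, width = width))
}

test_that("UR/MR peak sets partition with the read-count rule", {
    ur <- mkPeaks(c(1001L, 5001L))
    mr <- mkPeaks(c(1001L, 5001L))
    # bin tables covering the region; UR chip counts control the labels
    urBins <- makeBinTable(chip = rep(5L, 50), input = rep(5L, 50))
    mrBins <- makeBinTable(chip = rep(5L, 50), input = rep(5L, 50))
    cmp <- comparePeakSets(ur, mr, urBins, mrBins)
    expect_equal(length(cmp$common), 4L)  # both copies of both peaks
    expect_equal(length(cmp$mr_only), 0L)
    expect_equal(length(cmp$ur_only), 0L)
    expect_equal(length(cmp$ambiguous), 0L)

    # MR peak with no UR overlap: UR count 19 -> MR-only, 20 -> ambiguous
    mr2 <- mkPeaks(c(8201L))          # covers bins 42-43 (start 8201, 8401)
    chipUR <- rep(0L, 50)
    chipUR[42] <- 19L
    urBins19 <- makeBinTable(chip = chipUR, input = rep(5L, 50))
    cmp19 <- comparePeakSets(mkPeaks(1001L), mr2, urBins19, mrBins)
    expect_equal(length(cmp19$mr_only), 1L)
    chipUR[42] <- 20L
    urBins20 <- makeBinTable(chip = chipUR, input = rep(5L, 50))
    cmp20 <- comparePeakSets(mkPeaks(1001L), mr2, urBins20, mrBins)
    expect_equal(length(cmp20$mr_only), 0L)
    expect_equal(length(cmp20$ambiguous), 1L)
    # the four lists partition the union
    tot <- length(cmp20$common) + length(cmp20$mr_only) +
        length(cmp20$ur_only) + length(cmp20$ambiguous)
    expect_equal(tot, 2L)
})

test_that("read profiles collapse within-peak multiple mappings", {
    df <- rbind(
        data.frame(read_id = "m1", chrom = "chr1", start = c(1010L, 1200L),
                   width = 36L, strand = "+", mismatches = 0L,
                   weight = c(0.3, 0.2)),
        data.frame(read_id = "m1", chrom = "chr1", start = 9000L,
                   width = 36L, strand = "+", mismatches = 0L, weight = 0.5),
        data.frame(read_id = "u1", chrom = "chr1", start = 1100L,
                   width = 36L, strand = "+", mismatches = 0L, weight = 1))
    x <- makeAlignments(df, weighted = TRUE)
    prof <- peakReadProfiles(mkPeaks(1001L), x)[[1]]
    expect_equal(nrow(prof), 2L)
    expect_equal(prof$weight[prof$read_id == "m1"], 0.5)
    expect_equal(prof$weight[prof$read_id == "u1"], 1)
    expect_true(prof$uni[prof$read_id == "u1"])
    expect_false(prof$uni[prof$read_id == "m1"])
    empty <- peakReadProfiles(mkPeaks(50000L), x)[[1]]
    expect_equal(nrow(empty), 0L)
})

profOf <- function(ids, weights, uni = NULL) {
    data.frame(read_id = ids, weight = weights,
               uni = if (is.null(uni)) rep(FALSE, length(ids)) else uni)
}

test_that("similarity matches its stated anchor properties", {
    # all shared weights 0.5/0.5: similarity = number of overlapping reads
    p1 <- profOf(sprintf("r%d", 1:8), rep(0.5, 8))
    p2 <- profOf(sprintf("r%d", 1:8), rep(0.5, 8))
    rec <- peakSimilarity(p1, p2)
    expect_equal(rec$similarity, 8)
    expect_equal(rec$similarity_normalized, 1)
    # self-similarity = total number of reads in the peak
    p3 <- profOf(sprintf("r%d", 1:5), c(1, 0.7, 0.5, 0.2, 0.1))
    self <- peakSimilarity(p3, p3)
    expect_equal(self$similarity, 5)
    # 0.9/0.1 contributes 0.2; 0.6/0.4 contributes 0.8
    a <- peakSimilarity(profOf("r1", 0.9), profOf("r1", 0.1))
    b <- peakSimilarity(profOf("r1", 0.6), profOf("r1", 0.4))
    expect_equal(a$similarity, 0.2)
    expect_equal(b$similarity, 0.8)
    expect_lt(a$similarity, b$similarity)   # 0.9/0.1 more different
})

test_that("similarity is symmetric and normalized into [0, 1]", {
    set.seed(71)
    for (i in 1:25) {
        na <- sample(3:10, 1); nb <- sample(3:10, 1)
        shared <- sample(2, 1) + 1
        ids_a <- c(sprintf("s%d", 1:shared),
                   sprintf("a%d", seq_len(na - shared)))
        ids_b <- c(sprintf("s%d", 1:shared),
                   sprintf("b%d", seq_len(nb - shared)))
        pa <- profOf(ids_a, runif(na))
        pb <- profOf(ids_b, runif(nb))
        ab <- peakSimilarity(pa, pb); ba <- peakSimilarity(pb, pa)
        expect_equal(ab$similarity, ba$similarity)
        expect_equal(ab$similarity_normalized, ba$similarity_normalized)
        expect_gte(ab$similarity_normalized, 0)
        expect_lte(ab$similarity_normalized, 1)
    }
})

test_that("the paired t-test matches a direct computation", {
    set.seed(72)
    for (i in 1:100) {
        n <- sample(3:20, 1)
        wi <- runif(n); wj <- runif(n)
        d <- wi - wj
        tstat <- mean(d) / (sd(d) / sqrt(n))
        want <- 2 * pt(abs(tstat), df = n - 1, lower.tail = FALSE)
        got <- peakSimilarity(profOf(sprintf("r%d", 1:n), wi),
                              profOf(sprintf("r%d", 1:n), wj))$t_pvalue
        expect_equal(got, want, tolerance = 1e-8)
    }
    # degenerate pairs report NA rather than erroring
    same <- peakSimilarity(profOf(c("r1", "r2"), c(0.5, 0.5)),
                           profOf(c("r1", "r2"), c(0.5, 0.5)))
    expect_true(is.na(same$t_pvalue) || is.nan(same$t_pvalue))
    single <- peakSimilarity(profOf("r1", 0.4), profOf("r1", 0.6))
    expect_true(is.na(single$t_pvalue))
})

test_that("MR-only classification reproduces hand-worked outcomes", {
    profiles <- list(
        # A: shares nothing with anyone -> Type-III
        A = profOf(sprintf("a%d", 1:10), rep(0.5, 10)),
        # B: shares with F, unshared multi-read mass 25 -> Type-II via (a)
        B = profOf(c(sprintf("s%d", 1:4), sprintf("b%d", 1:50)),
                   c(rep(0.5, 4), rep(0.5, 50))),
        # C: shares with F, 20 uni-reads, tiny unshared mass -> Type-II (b)
        C = profOf(c(sprintf("t%d", 1:4), sprintf("c%d", 1:20)),
                   c(rep(0.5, 4), rep(1, 20)),
                   uni = c(rep(FALSE, 4), rep(TRUE, 20))),
        # D: shares with F, unshared/shared ratio 3 -> Type-II via (c)
        D = profOf(c(sprintf("u%d", 1:4), sprintf("d%d", 1:12)),
                   c(rep(0.5, 4), rep(0.5, 12))),
        # E: shares heavily with F, no support -> Type-I
        E = profOf(c(sprintf("v%d", 1:10), "e1"),
                   c(rep(0.5, 10), 0.4)),
        # F: the partner peak holding the complementary halves
        F = profOf(c(sprintf("s%d", 1:4), sprintf("t%d", 1:4),
                     sprintf("u%d", 1:4), sprintf("v%d", 1:10)),
                   rep(0.5, 22)))
    cls <- classifyMROnly(profiles, c("A", "B", "C", "D", "E"))
    expect_equal(cls$type,
                 c("Type-III", "Type-II", "Type-II", "Type-II", "Type-I"))
    expect_equal(cls$criterion, c("none", "a", "b", "c", "none"))
    expect_equal(cls$partner[-1], rep("F", 4))
    # exhaustive and mutually exclusive by construction of the return value
    expect_false(any(is.na(cls$type)))
})

test_that("saturation rejects invalid fractions", {
    fx <- standardFixture(seed = 73L, genomeLen = 20000L, dupStart = 3001L,
                          dupWidth = 4000L, dupTarget = 14001L,
                          nUnique = 1L, nDup = 1L, depth = 800L)
    chip <- exactMultiMap(fx$sim$chip, fx$genome)
    inp <- exactMultiMap(fx$sim$input, fx$genome)
    expect_error(saturationAnalysis(chip, inp, fx$genome,
        GenomicRanges::GRanges(), fractions = c(0, 0.5)), "fractions")
    expect_error(saturationAnalysis(chip, inp, fx$genome,
        GenomicRanges::GRanges(), fractions = c(0.5, 1.5)), "fractions")
})
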