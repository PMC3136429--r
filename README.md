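# mrchip — multi-read allocation and peak detection for ChIP-seq

Standard ChIP-seq pipelines keep only *uni-reads* (tags aligning to a
single genomic location) and discard *multi-reads* (tags with several
candidate alignments). That choice silently blinds peak detection inside
segmental duplications — repeats ≥ 1 kb with ≥ 90% identity — where
binding sites generate almost no uni-reads regardless of sequencing
depth. `mrchip` rescues multi-reads and carries them through the whole
analysis:

* **Allocation.** Each multi-read's candidate alignments receive weights
  by an iterated rescue scheme: the fraction assigned to candidate
  position *p* is proportional to *N(p)*, the read mass from the previous
  iteration inside the window *[p − w, p + w]* (default *w* = 100 bp,
  200 synchronous iterations, uniform 1/k initialization, strand ignored,
  reads with ≥ 100 alignments dropped). Window sums are served by a
  Fenwick-tree count index over occupied positions.
* **Mappability & GC.** Per-position k-mer occurrence counts *n(x)* give
  uni-read mappability (Def 1: 1 iff *n(x)* = 1) and multi-read-aware
  mappability (Def 2: 1/*n(x)* for *n(x)* < 100, else 0), with
  fragment-length extension and bin-level averaging; GC content per bin.
* **Binning.** Strand-aware fragment extension to *L* (default 200 bp),
  fractional accumulation into 200 bp bins, configurable
  round/ceiling/floor integerization; UR (uni-only) and MR (uni + multi)
  tables.
* **Peak calling.** A conditional binomial test (X | X+Y binomial, null
  proportion from low-count bins, BH-controlled FDR) and a two-component
  negative-binomial mixture with background regression on mappability, a
  GC spline and log-input (posterior-probability FDR). Bound bins with
  < 30 ChIP tags are dropped; contiguous bound bins merge into peaks.
* **Downstream.** UR/MR peak-set comparison (MR-only = no UR overlap and
  UR count < 20), multi-read similarity between peaks (a shared read
  contributes 1 − |Δw|), Type-I/II/III classification of MR-only peaks,
  nested-subsample saturation analysis, promoter/genic/duplication
  annotation, IUPAC consensus-motif counting with a width/mappability/GC
  matched-null enrichment test, TSS aggregation profiles, and pseudo-read
  export (each multi-read once, at its max-weight location if ≥ 0.5) for
  uni-read-only tools.
* **Synthetic data.** Seeded generators for genomes with planted
  duplications, ChIP/input read sets with planted peaks, and a toy
  exhaustive multi-mapper, so everything above is testable end to end.

## Worked example

A 60 kb genome carries an exact 8 kb duplication (8,001–16,000 copied to
42,001–50,000) and two planted 300 bp binding sites at 20× enrichment —
one in unique sequence (25,000), one inside the duplication (10,000):

```r
library(mrchip)

g <- simulateGenome(c(chr1 = 60000L), duplications = data.frame(
    chrom = "chr1", start = 8001L, width = 8000L,
    target_chrom = "chr1", target_start = 42001L, identity = 1.0),
    seed = 11)
pk <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(25000L, 10000L), width = 300L))
S4Vectors::mcols(pk)$rate <- 20
sim <- simulateChipSeq(g$genome, pk, depth = 9000, readLength = 36,
                       fragLength = 200, seed = 12)

chip  <- exactMultiMap(sim$chip,  g$genome)
input <- exactMultiMap(sim$input, g$genome)
cw <- allocateMultiReads(chip,  w = 100, iterations = 200)
iw <- allocateMultiReads(input, w = 100, iterations = 200)
allocationSummary(cw)
#>   uni_reads multi_reads rescued_pct
#> 1      6228        2772    44.50867

track <- fragmentExtendMappability(
    nucleotideMappability(kmerOccurrences(g$genome, 36), "def2", k = 36),
    200)
bt <- assembleBinTable(extendAndBin(cw, g$genome, 200, 200, "MR"),
                       extendAndBin(iw, g$genome, 200, 200, "MR"),
                       binScores(track, 200), binScores(g$genome, 200))
peaks <- callPeaks(cbTest(bt), bt, fdr = 0.05, minChipCount = 30)
as.data.frame(peaks)[, c("start", "end", "score", "chip_sum",
                         "avg_log2_enrichment", "mappability")]
#>   start   end         score chip_sum avg_log2_enrichment mappability
#> 1  9801 10400  6.020660e-64      882            2.064834         0.5
#> 2 24801 25400 3.925534e-164     1691            2.972672         1.0
#> 3 43801 44400  1.276247e-63      884            2.054594         0.5
```

31% of the reads are multi-reads (`rescued_pct` ≈ 44.5% of the uni-read
count), and the MR analysis finds both planted sites. The peak inside the
duplication appears in *both* copies (rows 1 and 3) with half the count
mass each and mappability 0.5 — the signature of an exactly duplicated
binding site, which the similarity/classification machinery
(`peakReadProfiles()`, `peakSimilarity()`, `classifyMROnly()`) then flags
as a mirrored pair. A uni-read-only analysis of the same data calls only
the unique-sequence peak.

A thin command-line front end over the same functions is provided in
`inst/scripts/mrchip.R` (subcommands `allocate`, `mappability`, `bin`,
`callpeaks`).

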