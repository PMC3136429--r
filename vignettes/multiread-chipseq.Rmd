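---
title: "Multi-read allocation and peak detection with mrchip"
author: "mrchip authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-read allocation and peak detection with mrchip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrchip)
```

# The problem

ChIP-seq analysis conventionally keeps only *uni-reads* — tags that align
to a single genomic location at the chosen mismatch threshold — and
discards *multi-reads*, tags with several candidate alignments.  In
genomes with recent segmental duplications (repeats of 1 kb or more with
at least 90% identity to another locus) this is not a harmless loss of
depth: a binding site inside a duplication produces almost no uni-reads at
all, so no amount of additional sequencing makes it visible to a
uni-read-only analysis.  `mrchip` implements a complete pipeline for
rescuing multi-reads: probabilistic allocation of each multi-read across
its candidate alignments, mappability- and GC-aware bin-level count
construction, peak calling, and the downstream comparisons needed to
interpret peaks that only appear once multi-reads are used.

# The allocation model

Every read is aligned in report-all mode (all alignments with at most a
configured number of mismatches, 2 by default).  Reads with 100 or more
candidate alignments are discarded.  Strand is ignored for allocation: the
leftmost coordinate of each alignment is its position.

The allocator maintains a fractional count field $c(j)$ over all genomic
positions at which at least one alignment starts.  Uni-reads contribute a
fixed count of 1 at their position.  For a multi-read with candidate
positions $p_1, \dots, p_k$, the fraction assigned to $p_i$ at the next
iteration is

$$ f_i' \;=\; \frac{N(p_i)}{\sum_{j=1}^{k} N(p_j)}, \qquad
   N(p) \;=\; \sum_{|j - p| \le w} c(j), $$

i.e. proportional to the read mass inside the window of half-width $w$
centered on the candidate.  Updates are *synchronous*: all fractions are
recomputed from the complete previous count field before any is applied,
which makes the result independent of read order.  Fractions are
initialized uniformly at $1/k$, and if every candidate window is empty the
uniform fallback is kept.  The iteration runs for a fixed 200 rounds by
default; the final fractions are reported as alignment weights.  This is
an iterated "rescue" scheme and can be read as a heuristic EM: the count
field plays the role of the E-step's expected coverage, the proportional
reassignment the M-step.

Window sums are served by a Fenwick-tree index (`CountIndex`) storing only
occupied positions, so one iteration costs $O(A \log n)$ for $A$
alignments over $n$ stored positions.  The same index is exported
(`countIndex()`, `windowSum()`, `indexAdd()`) and is verified in the tests
against naive summation.

**Parameter choices.** `w` (bp, default 100) controls how far uni-read
evidence reaches; it should satisfy $2w \le L$ (fragment length) so the
uni-reads and multi-reads inside one window belong to the same binding
event — the package warns when this is violated.  The candidate set for
`w` in the underlying method is 25–100 bp; we default to the largest value
compatible with $2w \le L = 200$.  The iteration count (200) is kept fixed
by default for reproducibility; an optional convergence tolerance on the
maximum weight change can stop early.  In the closed-form test
configuration (a uni-read neighbor at one of two candidate sites) the
favored weight follows $f' = (1+f)/2$, converging geometrically to 1 —
this recursion is asserted to $10^{-12}$ in the tests.

# Mappability and GC content

For tag length $k$, $n(x)$ counts the occurrences of the $k$-mer starting
at $x$ over both strands of the genome.  Two per-position scores are
derived: **def1** (uni-read mappability) is $1$ iff $n(x) = 1$; **def2**
(multi-read-aware) is $1/n(x)$ for $n(x) < 100$ and $0$ otherwise,
mirroring the cap above which reads are discarded.  Because counting is
double-stranded, the reverse-strand score at $x$ equals the forward score
at $x - k + 1$.

After fragment extension, the count at a position $x$ can originate from
forward-strand tags starting at any of the $L$ positions ending at $x$, or
reverse-strand tags whose 5' end lies in the $L$ positions from $x$
onward.  The extended score is the mean of per-start scores over those up
to $2L$ contributing starts.  The exact normalizing constants of the
published definition are not available to us; we adopt the mean over the
*in-genome* contributing starts, which preserves the $[0,1]$ range and
handles chromosome ends by dividing by the actual number of contributors.
Bin-level mappability and GC content are plain averages over bin
positions; bins consisting only of N are excluded, and GC is the G/C
fraction among non-N bases.

# Bin-level counts

Each weighted alignment is extended strand-aware to the fragment length
$L$ (forward `[start, start+L)`, reverse `(end-L, end]`, clipped at
chromosome ends) and its weight is added to **every** bin its fragment
overlaps — the literal reading of "reads overlapping each bin".  The UR
(uni-read) table uses uni-reads only; the MR table adds the allocated
multi-reads fractionally.  Fractional sums are made integer with a
configurable rule; "round" is implemented half-away-from-zero, with
ceiling and floor as bounding alternatives, and on the standard fixture
the peak sets under the three rules agree with Jaccard ≥ 0.9.  Bin size
defaults to 200 bp, matched to the expected fragment length; the usual
working range is 50–250 bp and values outside it warn.

# Peak calling

Two callers operate on the same `BinTable`.

**Conditional binomial.** Under independence of ChIP count $X$ and input
count $Y$ in an unbound bin, $X \mid X+Y$ is binomial with proportion
$p_0$, estimated as the ratio of total ChIP to total tags over bins with
$X + Y \le 1$ (threshold configurable; a degenerate estimate falls back to
the global depth ratio with a warning).  Per-bin upper-tail p-values are
corrected by Benjamini–Hochberg — the multiple-testing mechanism is our
choice, made because it is the standard way to control FDR over bin-level
p-values.

**Negative-binomial mixture.** Background bins follow a negative binomial
whose log-mean is linear in mappability, a piecewise-linear B-spline in GC
(knots at the GC 1st and 3rd quartiles) and $\log(1 + \text{input})$;
bound bins add a shift constant (default 3, the minimum count expected in
a bound region) plus a mixture of two negative binomials.  Fitting is EM:
the background regression is re-fit each iteration weighted by the current
background responsibilities (a weighted `glm.fit` with a fixed-theta
negative-binomial family; dispersion re-estimated by method of moments),
and the two signal components are updated by posterior-weighted moments.
Signal components initialize at 5× and 20× the mean background level and
the fit is deterministic.  This is a deliberate simplification of the full
published mixture model (whose estimation equations we do not reproduce);
the simulation tests show it recovers a known mappability coefficient of
3.0 within ±10% at 50,000 bins and holds the realized FDR within 1.5× the
nominal level.  FDR control on the posterior scale declares the largest
bin set whose mean background posterior is at most the level.

Both callers then drop bound bins with fewer than 30 ChIP tags (default)
and merge contiguous bound bins into peaks, recording the summit bin, the
count sums, depth-scaled mean log2 enrichment (0.5 pseudocount), and mean
mappability/GC.

# Downstream comparisons

UR and MR peak sets are partitioned into common, MR-only, UR-only and
ambiguous: a non-overlapping MR peak is *MR-only* only when its UR read
count over the region is below 20, so that no plausible uni-read analysis
could have scored it; the symmetric rule defines UR-only.

For similarity, the reads in each peak are collapsed to a unique set with
within-peak weights summed.  A shared read contributes
$1 - |w_{ri} - w_{rj}|$ to the similarity of peaks $i$ and $j$.  The exact
published formula is not available; this form is forced by its three
stated anchor properties, all asserted in the tests: self-similarity
equals the peak's read count, all-0.5 weights give the overlap count, and
a 0.9/0.1 split separates peaks more than 0.6/0.4.  Scores are normalized
by the larger read count of the pair, and the weight symmetry of shared
reads is tested by paired t and Wilcoxon signed-rank tests.

MR-only peaks sharing no multi-read with any other peak are **Type-III**.
Otherwise a peak is evaluated against its maximum-similarity partner
(configurable to an all-partners mode) and is **Type-II** when (a) its
unshared multi-read mass is ≥ 20, or (b) it has ≥ 20 uni-reads, or (c)
its unshared/shared fractional-count ratio is ≥ 2; otherwise **Type-I**, a
candidate duplication artifact.  "Partner" is ambiguous when several peaks
share reads; we use the maximum-similarity partner because the similarity
score is the quantity the classification is about.

**Saturation** draws nested subsamples of the uni- and multi-read pools
(higher fractions are supersets by construction), re-runs the full
pipeline per subsample in UR and MR modes, and reports the percentage of
gold-standard peaks recovered.  The gold standard is called on the full
data at FDR 0.005 — the stricter level conventionally used for gold sets —
because at looser levels the gold list can contain marginal background
peaks that only exact self-recovery reproduces.

**Annotation** assigns each peak one category with precedence
PromDup > Prom > GenicDup > Genic > Dup > None.  The promoter half-width
default (±2 kb) is a configurable choice, not a fact of the underlying
study (whose value is not available); the genic window runs from 10 kb
upstream of the TSS to 1 kb downstream of the TES.  The "Dup" flavor
applies when the peak's gene resides in a segmental duplication or the
peak itself overlaps one; emptying the duplication set collapses the
categories exactly to Prom/Genic/None.

**Motif enrichment** counts IUPAC consensus occurrences (e.g. `WGATAR`)
on both strands and compares the proportion of peaks with a motif against
10,000 null peak sets, each matching every real peak in chromosome, exact
width, and mean mappability and GC within ±0.05 (tolerances our choice;
doubled with a warning when a peak is unmatchable).  The empirical
p-value uses the non-strict comparison so that a motif absent from the
genome yields p = 1 rather than a spurious 0.  Null sampling iterates
peaks in canonical coordinate order, making the p-value invariant to the
input ordering and deterministic under a seed.

**TSS profiles** average a strand-oriented window of bins around gene
TSSs and subtract the mean of the boundary bins (2 per end by default; 4
reproduces the wider variant), optionally stratified by duplicated versus
unduplicated genes.

# The synthetic-data module

`simulateGenome()` draws i.i.d. bases and plants duplication blocks with a
per-base substitution rate of $1-\text{identity}$.  `simulateChipSeq()`
draws fragments from a mixture of uniform background and planted peaks
(the mixture weight of a peak is $(\text{rate}-1) \times \text{width}$, so
read density inside a peak is `rate` times the flanking density), takes
the first $k$ bases on a uniformly chosen strand, and emits exactly the
requested depth; the matched input sample has uniform origins.
`exactMultiMap()` reports all alignments at the mismatch cap and agrees
with a position-by-position scan in the tests.

What this emulates — duplicated sequence, ambiguous alignment structure,
planted enrichment, matched input — is exactly what the pipeline's claims
are about.  What it does not emulate: PCR duplicates, non-uniform
fragmentation and GC amplification bias, realistic base-call error
profiles (the default error rate is 0 so ambiguity structure is exact),
paired ends, and real-genome repeat taxonomies.  Passing tests therefore
demonstrate correctness of the algorithms and their qualitative behavior
on duplicated genomes, not performance on any particular real dataset.

# Numerical choices and degenerate inputs

* Weights are serialized at 6 decimals; conservation is re-checked at
  1e-5 after read-back, and the in-memory invariant is 1e-9.
* Pseudo-read export emits each multi-read at most once, at its
  maximum-weight location when that weight is ≥ 0.5; an exact 0.5/0.5 tie
  resolves to the smallest (chromosome, start) so reads are never double
  counted.
* Fenwick-tree float drift is clamped so weights stay in [0, 1].
* Empty bins are retained in the mixture fit (they inform the background)
  but never declared bound; bins of pure N are excluded outright.
* `cbTest` with no informative low-count bins falls back to the global
  depth ratio with a warning — common on deeply sequenced small fixtures.
* The EM returns its best fit with a warning if not converged within
  `maxIter` (default 25).

# Problem sizes used in the checks

The packaged tests and the acceptance script run entirely on synthetic
data sized for quick, stable checks: 10,000 reads for allocation
invariants; a 100 kb tandem-duplicated genome for mappability; 10,000
null bins for calibration; 50,000 bins for mixture recovery; a 200 kb
genome with a 20 kb duplication, ten unique-region and ten
duplicated-region peaks at 20× enrichment and 30,000 reads per sample for
the end-to-end comparison; and a 60 kb fixture for saturation.  These
sizes were chosen as the smallest at which the statistical assertions are
comfortably stable.

# Known limitations

* The mixture caller is a simplified re-derivation, not a reimplementation
  of the published estimation equations; per-chromosome tuning-parameter
  selection by BIC is not included (one fit per dataset).
* Occurrence counting and the toy multi-mapper target desk-scale genomes
  (megabases), not full mammalian genomes.
* Paired-end data, alignment quality scores and base-call qualities are
  out of scope; the allocation uses positions only.
* The exact window half-width, fragment-extension constants, similarity
  formula and promoter width of the underlying study are not published in
  the text available to us; the choices here are documented above and are
  configurable rather than silently fixed.
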