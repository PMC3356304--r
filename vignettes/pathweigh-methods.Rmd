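---
title: "Gene-length-aware pathway enrichment for per-sample somatic mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-length-aware pathway enrichment for per-sample somatic mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathweigh)
```

## The problem

Pathway enrichment tests ask whether a gene list of interest hits a gene
set more often than chance. The classical answer — the hypergeometric
(one-sided Fisher) test — models the genes as balls in an urn, every ball
equally likely to be drawn. For per-sample somatic mutation data that
assumption fails structurally: mutations land on nucleotides, roughly
uniformly at a background rate $\mu$ per position, so a gene of length
$l_i$ carries at least one mutation with probability

$$m_i \;=\; 1 - e^{-\mu\, l_i},$$

which increases with gene length. Long genes are mutated more often purely
because they are bigger targets, and pathways rich in long genes (axon
guidance is the canonical offender in cancer panels) are systematically
over-called by urn-model tests.

`pathweigh` tests pathway enrichment per sample against a null that keeps
that length structure. For a sample with $N$ mutated genes ("MutGenes")
out of a universe of $n$ assayed genes, it rebuilds the null by weighted
label randomization: each randomization draws $N$ genes without
replacement with selection weights $m_i$, so null MutGene sets show the
same gene-length pattern as real ones. The observed overlap $k$ of the
sample's MutGenes with a pathway is then compared with the overlap counts
$K$ across $B$ randomizations.

## The weighted resampling null

Each randomization draws one uniform variate $u_i$ per gene and forms the
key $u_i^{1/m_i}$; the $N$ genes with the largest keys become the null
MutGenes. Larger $m_i$ pulls the key toward 1, so longer genes are
selected more often; with all $m_i$ equal the scheme reduces exactly to
uniform sampling. This exponent-key construction is the standard weighted
sampling-without-replacement scheme and coincides with successive
sampling: the first gene is picked with probability $m_i / \sum_j m_j$,
the next proportionally among the rest, and so on. For two genes and
$N = 1$, $P(\text{gene } a) = m_a / (m_a + m_b)$ — the identity the test
suite checks against exhaustive enumeration. Ties between keys have
probability zero with a continuous generator; the implementation breaks
them by universe order for reproducibility.

The empirical enrichment P value uses the add-one exceedance estimator

$$\hat p \;=\; \frac{\#\{\pi : K(\pi) \ge k\} + 1}{B + 1},$$

which counts the observed labelling as one more realization of the null.
It can never be zero, so Bonferroni correction across pathways stays
meaningful; a `raw` option gives $\#\{K \ge k\}/B$ for comparisons against
analytic values. Two baselines are always available: *regular*
(unweighted) resampling — the same construction with equal weights — and
the analytic hypergeometric upper tail. With equal gene lengths all three
agree, a limit the acceptance suite verifies at $B = 10^5$.

One set of draws per (sample, scheme) is shared across all pathways and
re-used by the crosstalk statistic; marginally this is identical to fresh
draws per pathway and much cheaper. Draws come from a per-sample RNG
sub-stream derived deterministically from the base seed and the sample id,
so adding or removing a sample never changes another sample's results.

## Parameters that matter

* `mu` — background mutation rate per nucleotide, order $10^{-6}$.
  It is an input, not estimated: published per-cohort values (e.g.
  $2.7\times10^{-6}$ for a lung adenocarcinoma panel; $3.7\times10^{-6}$ /
  $6.4\times10^{-6}$ for untreated/treated glioblastoma) are typical. A
  per-sample map (`mu = c(s1 = ..., .default = ...)`) supports
  heterogeneous cohorts. Within one sample, $\mu$ is a monotone
  transformation of length into weight; across samples it puts tests on a
  common scale, which matters for the co-mutation map.
* Gene `length` — user-supplied, in nucleotides. Any consistent convention
  (genomic span, coding length) is acceptable; the package deliberately
  does not compute lengths from annotation, because the statistic should
  not silently depend on an annotation choice.
* The universe — the set of *assayed* genes. Resampling over genes that
  could never have been observed mutated would be invalid, so the universe
  is always explicit and mutated genes missing from it are dropped with a
  warning (no length means no weight).
* Pathway size bounds — default 10–500 universe-resident members, the
  conventional band excluding overly specific and overly general sets.
  The filter applies after intersection with the universe.
* `min_mut_genes` — samples with fewer universe-resident MutGenes are
  excluded (default 10; a looser 5 suits sparsely mutated cohorts). Small
  $N$ gives the test no resolution.
* `n_resamples` — default 10,000. The smallest attainable P is
  $1/(B+1)$; choose $B$ so that the Bonferroni threshold
  $\alpha / \#\text{pathways}$ stays well above it.

## Crosstalk and the co-mutation map

Within a sample, two enriched pathways may be driven by the same mutated
genes. The crosstalk statistic is the Jaccard coefficient of the
*mutated* members, $JC = |U \cap V| / |U \cup V|$ with
$U = \text{MutGenes} \cap A$ and $V = \text{MutGenes} \cap B$, scored
against the same weighted draws: in resample $\pi$ the draw plays the role
of the MutGene set, and $p = (\#\{JC(\pi) \ge JC_{obs}\} + 1)/(B+1)$.
Computing $JC$ on mutated members rather than full memberships is the
choice that makes the null informative — full memberships are constant
across resamples (that static coefficient is available via
`jc_on = "full"` for reporting). Edges are flagged at nominal
$p < 0.05$: Bonferroni-corrected crosstalk P values are essentially never
significant at practical $B$, so nominal selection is the default
reporting rule. Hub genes shared by many pathways (the *TP53*/*KRAS*
pattern) produce cliques of crosstalk edges; the suite constructs exactly
that fixture and checks the clique appears.

Across samples, each pathway's per-sample status is the binary indicator
"significantly enriched by the weighted method (Bonferroni < 0.05)". For
a pathway pair the samples split into the four cells of a 2×2 table (both
/ A only / B only / neither); Fisher's exact test (two-sided by default —
"associated" does not presuppose a direction; `alternative = "greater"`
tests pure co-occurrence) gives the edge P value, and an edge is retained
when the pair co-occurs in at least 2 samples with $P < 0.05$. Only
pathways significant somewhere, and samples with at least one significant
pathway, enter the profile: indicator noise from never-significant
pathways would dilute the map.

## The synthetic cohort generator

`simulate_cohort()` is the package's test bed and emulates exactly the
model the method assumes: every gene mutates independently with
probability $m_i = 1 - e^{-\mu l_i}$ (the collapsed, per-gene form of a
uniform per-nucleotide process; a `per_nucleotide` mode simulates
position-wise Binomial counts to cross-validate the equivalence). Lengths
are log-uniform over a configurable range (default 500–50,000 nt, median
≈ 5 kb). Planted *driver* pathways multiply their members' probabilities
(multiplier ≥ 1, capped so probabilities stay below 1) in the samples
where they are planted, and are drawn from mid-length genes so detection
is not a length artefact; the *decoy* pathway is drawn from the longest
decile and never boosted, so any apparent signal it shows is pure length
bias. Samples with zero mutated genes are redrawn, so the simulated
$E[N]$ is $\sum m_i / (1 - \prod(1-m_i))$, the oracle the tests use.

What the generator does **not** emulate: trinucleotide signatures, hotspot
or clustered mutations, copy-number events, sample contamination, or
misannotated lengths. Passing tests therefore demonstrate correctness of
the statistics under the stated model, not robustness of biological
conclusions on real cohorts.

## Study designs used by the validation suite

Problem sizes were chosen as the smallest designs that measure each
property cleanly.

* *Type-I calibration and bias demonstration.* 1,000 null samples over an
  exome-scale universe of 6,000 genes (4,800 × 2 kb, 1,200 × 20 kb — a
  10× length disparity) at $\mu = 2.7\times10^{-6}$, with a decoy of
  1,000 long genes and $B = 500$. The decoy deliberately spans a large
  share of the total mutational weight: the overlap count is discrete, and
  a small decoy would pin its attained size far below the nominal level
  (with a 20-gene decoy the attained rate is ≈ 0.02 for *any* exact
  method — a granularity artefact, not evidence of miscalibration). With a
  wide null distribution the weighted test's rejection rate sits inside
  the three-sigma band around 0.05 while the hypergeometric test rejects
  the decoy in essentially every sample.
* *Planted-signal recovery.* 30 samples over 1,000 genes, two 20-gene
  driver pathways with multiplier 25 co-planted in samples 1–20 and a
  third planted in samples 21–30, plus a 20-gene decoy and 30 random
  background pathways; $B = 10{,}000$. The third driver keeps the
  complementary samples in the co-mutation profile — without it they carry
  no significant pathway, drop out of the profile, and the co-planted
  pair's 2×2 table degenerates (d = 0 makes Fisher's P equal 1 no matter
  how perfect the co-occurrence).
* *Method equivalence.* A 20-gene equal-length universe, $N = 5$,
  $B = 10^5$: weighted, regular and hypergeometric P values agree within
  Monte-Carlo error, and the hypergeometric tail is checked exactly
  against subset enumeration for every instance with $n \le 12$.

## Numerical choices and degenerate inputs

* $m_i$ is computed as `-expm1(-mu * length)`, accurate for
  $\mu l \ll 1$ where `1 - exp(...)` loses precision.
* $k = 0$ gives $p = 1$ under every method; a pathway disjoint from the
  universe is removed by the size filter (membership is intersected
  first).
* Jaccard of two empty sets (possible in degenerate resamples) is defined
  as 0 with a warning.
* Fisher tables with a zero margin admit a single configuration; the P
  value is 1 by convention, warned.
* Duplicate gene ids in a length file are an error by default
  (`duplicates = "keep-max"` opts into silent resolution); duplicate
  (sample, gene) mutation rows collapse to one MutGene.
* Key ties in the weighted sampler are broken by universe order.

## Known limitations

* The weighted null conditions on $N$ via successive sampling; the
  generative model conditioned on $N$ is the slightly different
  conditional-Bernoulli law. The discrepancy is second order in $m_i$
  (odds $m/(1-m)$ versus weight $m$) and is invisible at somatic rates
  ($m_i \lesssim 0.1$), but at artificially large $\mu$ the two laws
  separate.
* Bonferroni is the only multiplicity correction, matching the method's
  standard usage; pathway tests on overlapping sets are strongly
  dependent, so it is conservative.
* $\mu$ is a single number per sample: regional mutation-rate variation
  (replication timing, expression) is out of scope, as is estimating
  $\mu$ from the data.
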