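---
title: "Scanning HELP-style methylation ratios for differential loci"
author: "helpscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning HELP-style methylation ratios for differential loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helpscan)
```

## The measurement and the model

HELP-type assays digest genomic DNA with the methylation-sensitive enzyme
HpaII and, in parallel, with its methylation-insensitive isoschizomer MspI.
After amplification and hybridization, each assayed fragment yields a
log2(HpaII/MspI) ratio: fragments whose CCGG sites are methylated resist
HpaII and give low (negative) ratios; hypomethylated fragments give high
(positive) ratios. Empirically the genome-wide ratio distribution is
bimodal around zero, and the package's state caller uses exactly that
threshold: ratio < 0 is called *methylated*, ratio > 0 *hypomethylated*,
and a ratio of exactly 0 is a *boundary* call that is excluded from
state-change summaries — the states are defined by strict inequalities
only, which keeps the rule deterministic at the knife edge.

The scientific question is a matched two-group comparison: for each locus,
do cases differ from their matched controls? With k matched pairs and
within-pair differences $d_1,\dots,d_k$ (case minus control), the scan
computes

$$t = \frac{\bar d}{s_d/\sqrt{k}}, \qquad p = 2\,P\!\left(T_{k-1} \ge |t|\right),$$

per locus. Matching (by gender, gestational age, ethnicity) is what
justifies the paired form; the scan refuses sample sheets whose pair
structure is broken. Loci with fewer than two complete pairs get missing
statistics. A locus whose paired differences have zero spread around a
nonzero mean would formally give p = 0; the t distribution is undefined
there, so the scan reports a missing p with a `degenerate` flag rather
than an exact zero that a downstream threshold would always accept.

## Permutation calibration of the genome-wide threshold

Standard significance levels are meaningless across ~10^4–10^6 loci, and
the package does not apply an FDR correction; instead the threshold is
calibrated against an empirical null. Labels are relabelled and the whole
scan re-run; the quantity retained from each permutation is its minimum
p-value across loci. The significance threshold $\alpha^*$ is then the
largest value on the fixed ladder $\{5\times10^{-1}, 10^{-1},
5\times10^{-2}, 10^{-2},\dots\}$ strictly below the smallest p observed in
any permutation — the formal version of "no statistic under any
permutation reached a p-value this low". The ladder makes the choice
reproducible and matches how such thresholds are reported in print (for a
permutation floor of 1.5e-5 the rule yields 1e-5).

Two relabelling schemes are provided because the design admits both
readings. The default `within_pair_flip` swaps case/control labels
independently within each pair — the exact null of the paired test; with k
pairs there are only $2^k$ sign patterns, so for small k the package
enumerates all $2^k - 1$ non-identity patterns exhaustively instead of
sampling (requesting exhaustive enumeration beyond k = 20 is refused).
Per-locus permutation p-values count the identity labelling as one
permutation, so exhaustive values equal the all-pattern fraction exactly
and can never be zero. The alternative `full_relabel` shuffles group
labels across all samples (preserving group sizes) and applies an unpaired
equal-variance t-test, mirroring a randomization of subjects into two
groups. Reports name the scheme used.

## The ranking statistic

P-value order is noisy when within-pair spreads vary by orders of
magnitude across loci, so a second ordering is provided:

$$\text{score} = \frac{|\bar d|}{s_d + s_0},$$

the SAM-style moderated form in which the stabilization constant $s_0 \ge 0$
(default: the median of $s_d$ across loci) prevents tiny-variance loci
from dominating and shifts weight toward the fold-change (the mean shift
on the log scale). Scores are used exclusively to rank loci; they are
never converted to probabilities. At $s_0 = 0$ the score is
scale-invariant in the differences — a shape statistic, |t|/√k; only
$s_0 > 0$ makes amplitude matter. A locus with zero spread *and*
$s_0 = 0$ is reported as `Inf` and ranked first, with a warning.

## Annotation conventions

Internally every interval is 0-based half-open (BED convention); printed
locus keys such as `chr2:235526053-235526128` are 1-based inclusive and
converted only at I/O boundaries, so printed positions reproduce exactly.
Overlap flags require at least one shared base — abutting half-open
intervals do not overlap. Gene assignment is strand-aware: a locus is a
promoter hit (PRO) when it intersects the 10 kb window upstream of the
TSS, taken as $[\text{TSS} - 10\,\text{kb}, \text{TSS})$ on the + strand
and mirrored on −. The TSS base itself is assigned to the gene body, so
the window excludes it and nothing is double counted; the gene body (GB)
takes precedence over PRO for the same gene, while a locus in the
promoter windows of two opposite-strand genes (and no body) is a
bidirectional promoter (PRO2). Network-style enrichment uses the
right-tailed hypergeometric tail computed by exact summation, reported as
$-\log_{10} p$; because the reference-universe size of a knowledge base
is never derivable from the data, the universe is an explicit argument.

## The power machinery

For study planning the package treats a future locus as a two-sample
problem: cases $\sim N(\delta, \sigma)$, controls $\sim N(0, \sigma)$,
with defaults $\delta = 0.60$ and $\sigma = 0.32$ log2 units — the effect
scale that the effect-size estimator recovers from the most informative
loci of a scan. The test inside each replicate is the **unpaired**
two-sided equal-variance t-test: the planning model specifies independent
case and control draws, and the unpaired form is the one whose closed
form reproduces the tabulated small-n cells (paired variants do not).
`simulate_power()` estimates power as the fraction of replicates with
p < α (p from the t distribution, which keeps α = 1e-10 columns
computable); `analytic_power()` is its deterministic twin,

$$\text{power} = P\left(|T'_{2n-2,\;\mathrm{ncp}}| > t_{1-\alpha/2}\right),
\qquad \mathrm{ncp} = \frac{\delta}{\sigma\sqrt{2/n}},$$

evaluated through R's noncentral-t distribution function. The default
200,000 replicates give a binomial standard error of at most ~0.0011,
enough to resolve two printed decimals; the two routes are required to
agree within Monte Carlo error in the test suite. On the default grid
(n ∈ {5, 10, 15, 25, 35, 50, 100} × α ∈ {0.05, 1e-5, 1e-10}) the smallest
design reaching 90% power at α = 1e-5 is **25 subjects per group**, which
is the package's sample-size recommendation for effects of this subtlety.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` produces the statistical skeleton the analysis
assumes:

* a **bimodal baseline** per locus from a two-Gaussian mixture, means
  −2.0 (methylated) and +2.0 (hypomethylated) log2 units, component SDs
  0.8, methylated weight 0.55 — values chosen once to mimic the empirical
  two-peak shape of HELP ratios around the zero threshold and to put
  inter-sample Pearson correlations in the observed high band (R > 0.9)
  at realistic locus counts;
* a small **planted differential fraction**: each affected locus adds a
  shift of magnitude $\sim N(0.60, 0.20)$ log2 units, random sign (both
  hyper- and hypomethylation occur in real cohorts), to case samples
  only;
* independent within-group noise, SD 0.32 log2 units, per value;
* optionally, **sex-linked loci** on chrX/chrY with a large (3.0 log2
  unit) between-gender shift, so a gender comparison lights up the sex
  chromosomes qualitatively;
* deterministic wide spacing of loci (40 kb within a chromosome), so the
  companion track/gene fixtures planted around one locus can never touch
  a neighbour.

The generator separates the spread of *true* shifts across loci
(`effect_sd_across_loci`, 0.20) from the per-sample measurement noise
(`noise_sd`, 0.32) as two independent knobs, since estimates of an
effect-size distribution conflate them differently depending on design.
The companion `simulate_bisulphite()` links ratios to percent methylation
through a decreasing logistic (midpoint 0, slope −1, ±5 percentage points
of truncated noise, clamped to [0, 100]) — the inverse relation between
the two platforms.

What the generator does **not** model: probe-level intensities, dye bias,
fragment-length effects, spatial artifacts, correlated loci (every locus
is independent), missingness mechanisms, or population structure beyond
the planted labels. Passing the recovery tests therefore demonstrates
that the statistics do what they claim on data satisfying their own
assumptions — not that a real array's artifacts are handled.

## Numerical and design choices

* Quantile normalization drops loci with any missing value first (count
  logged) and resolves ties by assigning the mean of the tied target
  quantiles; both choices are the standard deterministic ones. The
  implementation delegates to limma's quantile routine behind the package
  surface and is tested against an independent sort-average-reassign
  oracle.
* Array centering is by **median** (configurable intent: the robust
  choice when a minority of loci shift); centering is idempotent.
* Ward clustering is `ward.D2` on Euclidean distances — the variant that
  operates on the distances themselves, whose merge heights equal
  $\sqrt{2\,\Delta\mathrm{ESS}}$ and match a from-scratch minimum-variance
  oracle in the tests.
* Pearson QC correlations use pairwise-complete loci; a zero-variance
  sample yields a missing correlation rather than an error.
* All randomness flows through explicit integer seeds; the pipeline
  derives per-stage seeds from one global seed by hashing the stage name,
  so a single number reproduces a whole run.
* Test-suite problem sizes are deliberately modest (10^4-locus null
  calibrations, 2,000-locus recovery cohorts at 25 pairs, 200,000-replicate
  power cells): large enough for the stated statistical tolerances, small
  enough to re-run routinely.

## Known limitations

Region-level smoothing and DMR segmentation are out of scope — the scan is
strictly per locus. Covariates beyond the matching are not modelled. The
permutation floor with few pairs is coarse (31 non-identity patterns at
k = 5), so the calibrated threshold is conservative and small studies may
legitimately find nothing genome-wide significant — that observation is
precisely what motivates the power module's recommendation of larger
designs. The enrichment score reproduces the ranking statistic of
commercial network tools but not their knowledge bases or network-growing
heuristics.
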