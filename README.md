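# helpscan

Genome-wide differential DNA-methylation analysis for restriction-digest
(HELP-style) methylation arrays, aimed at matched case/control designs such
as cohorts of growth-restricted (IUGR) versus normal-birthweight neonates.
The assay compares genomic representations cut by the methylation-sensitive
HpaII enzyme against its methylation-insensitive isoschizomer MspI; each
locus is summarized as a log2(HpaII/MspI) ratio, with low ratios indicating
methylation and high ratios hypomethylation.

The package covers the full analysis path on such a ratio matrix:

* **Normalization and QC** — quantile normalization, per-array median
  centering, pairwise inter-sample Pearson correlations, Ward
  minimum-variance clustering of samples.
* **Differential scan** — per-locus paired t-tests across matched pairs:
  for within-pair differences d₁,…,d_k the statistic is
  t = mean(d) / (sd(d)/√k) with a two-sided p from the t distribution on
  k−1 df. Genome-wide significance is calibrated by permutation: labels are
  relabelled (within-pair flips by default, exhaustively when 2^k is small),
  and the threshold α\* is the largest round value strictly below the
  smallest p seen in any permutation. Candidates split into a significant
  (p < α\*) and a moderate tier.
* **Ranking** — a fold-change-weighted score |mean(d)| / (sd(d) + s₀), the
  SAM-style moderated form with s₀ defaulting to the median spread; used
  only to order loci, never as a probability.
* **Annotation** — overlap flags against CpG-island / CG-cluster /
  conserved / repeat BED tracks; strand-aware gene assignment (promoter =
  10 kb upstream of the TSS, gene body, bidirectional promoter);
  right-tailed hypergeometric enrichment scores (−log10 p).
* **Effect size and power** — the mean/SD of |difference| over the most
  informative loci, and two-sample t-test power by Monte Carlo and by the
  noncentral-t closed form: power = P(|T′| > t_crit) with df = 2n−2 and
  noncentrality δ/(σ√(2/n)).
* **Concordance** — correlation of array ratios with bisulphite percent
  methylation (expected strongly negative) and site-level group tests.
* **Synthetic cohorts** — a generator with planted ground truth (bimodal
  baseline, shifts ~ Normal(0.60, 0.20) log2 units on cases, noise SD
  0.32) so every stage is testable end to end without external data.

## Worked example

```r
library(helpscan)

cfg <- simulation_config(n_loci = 5000, n_pairs = 25,
                         frac_differential = 0.01, seed = 17)
cohort <- simulate_cohort(cfg)                      # 50 planted loci
norm   <- quantile_normalize(cohort$matrix)
stats  <- paired_t_scan(norm, cohort$samples)
null   <- permutation_null(norm, cohort$samples, n_perm = 200, seed = 17)
thr    <- significance_threshold(null)
cand   <- select_candidates(stats, thr$alpha_star)

thr$permutation_min_p   # 8e-07  (smallest p in any permutation)
thr$alpha_star          # 5e-07  (largest round threshold below it)
nrow(cand$significant)  # 25 significant, 5 moderate candidates

eff <- estimate_effect_distribution(stats, top_k = 50)
round(c(eff$mean_abs_difference, eff$sd_abs_difference), 2)  # 0.61 0.23
```

The permutation floor of 8e-07 across 200 relabellings calibrates the
genome-wide threshold to 5e-07; 25 of the 50 planted differential loci
clear it at this depth of permutation, and the top-50 effect-size summary
recovers the planted Normal(0.60, 0.20) shift distribution (mean 0.61, SD
0.23, 96% of loci in the subtle 0.20–1.00 log2 band).

Study planning from the closed form:

```r
analytic_power(25, delta = 0.60, sigma = 0.32, alpha = 1e-5)   # 0.937
recommend_sample_size(power_grid(method = "analytic"))         # 25
```

At a genome-scale significance level of 1e-5, 25 subjects per group is the
smallest tabulated design reaching 90% power for a 0.60 log2-unit shift
against a within-group SD of 0.32.

A whole run (simulate → normalize → qc → scan → annotate → power →
concord) can be driven from a YAML config via `run_pipeline()` or the
`inst/scripts/helpscan.R` command-line wrapper; every artifact lands in the
output directory together with a JSON provenance record.

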