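# Synthetic matched-cohort generator. Emulates the statistical structure of a
# restriction-digest (HELP-style) methylation screen on matched case/control
# neonates: a bimodal baseline log-ratio distribution (methylated fragments
# around -2, hypomethylated around +2), a small planted fraction of
# differential loci with per-locus mean shifts ~ Normal(0.60, 0.20) log2
# units of random sign applied to cases, and within-group per-sample noise
# with SD 0.32 log2 units.

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study conditions the package's analyses assume:
#' effect shifts drawn from Normal(0.60, 0.20) log2 units, within-group
#' noise SD 0.32, and a two-component baseline mixture with means -2
#' (methylated) and +2 (hypomethylated).
#'
#' @param n_loci number of loci.
#' @param n_pairs number of matched case/control pairs (>= 2).
#' @param frac_differential fraction of loci carrying a true shift, in
#'   `[0, 1]`.
#' @param effect_mean mean of the per-locus true |shift|, log2 units.
#' @param effect_sd_across_loci SD of the per-locus true shift across loci.
#' @param noise_sd within-group per-sample noise SD, log2 units.
#' @param baseline_means two component means of the baseline mixture
#'   (methylated, hypomethylated).
#' @param baseline_sds two component SDs.
#' @param baseline_weight mixing weight of the methylated component.
#' @param gender_effect if `TRUE`, a fraction of loci are placed on
#'   chrX/chrY and given a large between-gender shift, to emulate the
#'   sex-chromosome signal a gender comparison should recover.
#' @param gender_frac fraction of loci placed on sex chromosomes when
#'   `gender_effect` is on.
#' @param gender_shift log2 shift applied to male samples at sex-chromosome
#'   loci.
#' @param seed integer seed; every simulation call is reproducible given the
#'   config.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(n_loci = 10000, n_pairs = 5,
                              frac_differential = 0.01,
                              effect_mean = 0.60, effect_sd_across_loci = 0.20,
                              noise_sd = 0.32,
                              baseline_means = c(-2.0, 2.0),
                              baseline_sds = c(0.8, 0.8),
                              baseline_weight = 0.55,
                              gender_effect = FALSE, gender_frac = 0.02,
                              gender_shift = 3.0,
                              seed = 1L) {
  cfg <- list(n_loci = n_loci, n_pairs = n_pairs,
              frac_differential = frac_differential,
              effect_mean = effect_mean,
              effect_sd_across_loci = effect_sd_across_loci,
              noise_sd = noise_sd, baseline_means = baseline_means,
              baseline_sds = baseline_sds, baseline_weight = baseline_weight,
              gender_effect = isTRUE(gender_effect),
              gender_frac = gender_frac, gender_shift = gender_shift,
              seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  chk <- function(ok, field, why) if (!ok) stop("invalid '", field, "': ", why)
  chk(length(cfg$n_loci) == 1 && cfg$n_loci >= 1, "n_loci", "must be >= 1")
  chk(length(cfg$n_pairs) == 1 && cfg$n_pairs >= 2, "n_pairs", "must be >= 2")
  chk(cfg$frac_differential >= 0 && cfg$frac_differential <= 1,
      "frac_differential", "must be in [0, 1]")
  chk(cfg$effect_sd_across_loci > 0, "effect_sd_across_loci", "must be > 0")
  chk(cfg$noise_sd > 0, "noise_sd", "must be > 0")
  chk(all(cfg$baseline_sds > 0), "baseline_sds", "must be > 0")
  chk(cfg$baseline_weight >= 0 && cfg$baseline_weight <= 1,
      "baseline_weight", "must be in [0, 1]")
  chk(!is.na(cfg$seed), "seed", "must be an integer")
  cfg
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a matched case/control methylation cohort
#'
#' Per locus, a baseline ratio is drawn from the two-component mixture;
#' differential loci add a signed per-locus shift (|shift| ~
#' Normal(`effect_mean`, `effect_sd_across_loci`), sign random) to the case
#' samples only; every value then receives independent Normal(0, `noise_sd`)
#' noise. Ground truth is returned for recovery testing.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `matrix` (a [methylation_matrix()]),
#'   `samples` (sample sheet data.frame) and `truth` (per-locus
#'   `is_differential`, `true_shift`, `sex_linked`).
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_loci = 50, seed = 7))
#' table(cohort$truth$is_differential)
#' @export
simulate_cohort <- function(config) {
  cfg <- validate_simulation_config(config)
  with_seed(cfg$seed, {
    n <- cfg$n_loci
    k <- cfg$n_pairs

    autosomes <- paste0("chr", 1:22)
    chrom <- autosomes[(seq_len(n) - 1L) %% 22L + 1L]
    n_sex <- 0L
    if (cfg$gender_effect) {
      n_sex <- max(1L, round(cfg$gender_frac * n))
      sex_idx <- seq_len(n_sex)   # first loci are designated sex-linked
      chrom[sex_idx] <- rep(c("chrX", "chrY"), length.out = n_sex)
    }
    # wide deterministic spacing so planted gene/track fixtures near one locus
    # can never reach a neighbouring locus on the same chromosome
    within <- stats::ave(seq_len(n), chrom, FUN = seq_along)
    start <- (within - 1L) * 40000L + 1000L
    width <- sample(100:1500, n, replace = TRUE)
    loci <- data.frame(locus_id = format_locus_keys(chrom, start, start + width),
                       chrom = chrom, start = start, end = start + width,
                       strand = "*", stringsAsFactors = FALSE)

    samples <- data.frame(
      sample_id = c(sprintf("case_%02d", seq_len(k)),
                    sprintf("control_%02d", seq_len(k))),
      group = rep(c("case", "control"), each = k),
      pair_id = rep(sprintf("P%02d", seq_len(k)), 2),
      gender = rep(rep(c("M", "F"), length.out = k), 2),
      ethnicity = rep(rep(c("Latino", "non-Latino"), length.out = k), 2),
      stringsAsFactors = FALSE
    )

    comp <- stats::rbinom(n, 1, 1 - cfg$baseline_weight) + 1L  # 1 = methylated
    baseline <- stats::rnorm(n, cfg$baseline_means[comp], cfg$baseline_sds[comp])

    n_diff <- round(cfg$frac_differential * n)
    diff_idx <- if (n_diff > 0)
      sample(setdiff(seq_len(n), seq_len(n_sex)), n_diff) else integer()
    shift <- numeric(n)
    if (n_diff > 0) {
      shift[diff_idx] <- stats::rnorm(n_diff, cfg$effect_mean,
                                      cfg$effect_sd_across_loci) *
        sample(c(-1, 1), n_diff, replace = TRUE)
    }

    values <- matrix(baseline, nrow = n, ncol = 2 * k)
    values[, seq_len(k)] <- values[, seq_len(k)] + shift
    if (n_sex > 0) {
      male <- samples$gender == "M"
      values[seq_len(n_sex), male] <- values[seq_len(n_sex), male] + cfg$gender_shift
    }
    values <- values + stats::rnorm(length(values), 0, cfg$noise_sd)
    dimnames(values) <- list(loci$locus_id, samples$sample_id)

    truth <- data.frame(locus_id = loci$locus_id,
                        is_differential = shift != 0,
                        true_shift = shift,
                        sex_linked = seq_len(n) <= n_sex,
                        stringsAsFactors = FALSE)

    list(matrix = methylation_matrix(values, loci),
         samples = samples, truth = truth)
  })
}

#' Simulate annotation tracks and gene models with planted overlaps
#'
#' Builds toy CpG-island / CG-cluster / conserved / repeat tracks and gene
#' models placed deterministically relative to the cohort's loci, so that
#' known subsets overlap each feature. The planted overlap map is returned
#' for downstream assertions: loci are assigned cyclically to features
#' (every 5th locus gets a CpG island over it, etc.), and genes are placed
#' to exercise promoter, gene-body and bidirectional-promoter assignment.
#'
#' @param cohort the list returned by [simulate_cohort()].
#' @param upstream_window promoter window used when planting PRO loci
#'   (default 10000, the assignment rule's window).
#' @return list with `tracks` (named list of `AnnotationTrack`), `genes`
#'   (gene model data.frame) and `planted` (per-locus expected flags and
#'   gene category).
#' @export
simulate_annotation_tracks <- function(cohort, upstream_window = 10000) {
  loci <- cohort$matrix$loci
  n <- nrow(loci)
  idx <- seq_len(n)

  cover <- function(sel) loci[sel, c("chrom", "start", "end")]
  in_cpg <- idx %% 5L == 0L
  in_cgc <- idx %% 4L == 0L
  in_cons <- idx %% 3L == 0L
  in_rt <- idx %% 7L == 0L
  in_lt <- idx %% 11L == 0L

  mk <- function(name, kind, sel) {
    iv <- cover(sel)
    iv$strand <- "*"
    annotation_track(name, kind, iv)
  }
  tracks <- list(
    cpg = mk("cpg_islands", "CpG_island", in_cpg),
    cgc = mk("cg_clusters", "CG_cluster", in_cgc),
    cons = mk("conserved", "conserved", in_cons),
    rep_rt = mk("repeats_rt", "repeat_RT", in_rt),
    rep_lt = mk("repeats_lt", "repeat_LT", in_lt)
  )

  # Gene placement: cycle loci through PRO (+ strand TSS a few kb downstream
  # of the locus), GB (body spanning the locus), PRO2 (two opposite-strand
  # genes sharing the locus's neighbourhood), none.
  role <- rep(c("PRO", "GB", "PRO2", "none"), length.out = n)
  genes <- list()
  gi <- 0L
  for (i in idx) {
    L <- loci[i, ]
    if (role[i] == "PRO") {
      gi <- gi + 1L
      tss <- L$end + 5000
      genes[[gi]] <- data.frame(symbol = sprintf("GENE%04d", gi),
                                transcript = sprintf("NM_%06d", gi),
                                chrom = L$chrom, start = tss, end = tss + 4000,
                                strand = "+")
    } else if (role[i] == "GB") {
      gi <- gi + 1L
      genes[[gi]] <- data.frame(symbol = sprintf("GENE%04d", gi),
                                transcript = sprintf("NM_%06d", gi),
                                chrom = L$chrom, start = max(0, L$start - 500),
                                end = L$end + 500, strand = "+")
    } else if (role[i] == "PRO2") {
      tssp <- L$end + 3000
      gi <- gi + 1L
      genes[[gi]] <- data.frame(symbol = sprintf("GENE%04d", gi),
                                transcript = sprintf("NM_%06d", gi),
                                chrom = L$chrom, start = tssp, end = tssp + 2000,
                                strand = "+")
      gi <- gi + 1L
      tssm_end <- max(1, L$start - 3000)      # - strand TSS = end - 1 < locus start
      genes[[gi]] <- data.frame(symbol = sprintf("GENE%04d", gi),
                                transcript = sprintf("NM_%06d", gi),
                                chrom = L$chrom,
                                start = max(0, tssm_end - 2000), end = tssm_end,
                                strand = "-")
    }
  }
  genes <- gene_models(do.call(rbind, genes))

  planted <- data.frame(locus_id = loci$locus_id,
                        cpg = in_cpg, cgc = in_cgc, cons = in_cons,
                        rep_rt = in_rt, rep_lt = in_lt,
                        category = role, stringsAsFactors = FALSE)
  list(tracks = tracks, genes = genes, planted = planted)
}

#' Simulate bisulphite percent-methylation measurements linked to a matrix
#'
#' Percent methylation is inversely related to the log2(HpaII/MspI) ratio:
#' high ratios mean hypomethylation. The link is logistic,
#' `percent = 100 * plogis(link_slope * (ratio - link_midpoint))` plus
#' truncated Gaussian noise, clamped to `[0, 100]`.
#'
#' @param matrix a `MethylationMatrix`.
#' @param link_midpoint ratio mapping to 50 percent (default 0, the
#'   methylation-state threshold).
#' @param link_slope logistic slope; must be negative (platform polarity).
#' @param noise_sd_percent SD of additive noise in percentage points.
#' @param seed integer seed.
#' @return A data.frame `locus_id`, `sample_id`, `percent`.
#' @export
simulate_bisulphite <- function(matrix, link_midpoint = 0, link_slope = -1,
                                noise_sd_percent = 5, seed = 1L) {
  stopifnot(inherits(matrix, "MethylationMatrix"))
  if (link_slope >= 0)
    stop("link_slope must be negative: ratio and percent methylation are inversely related")
  v <- matrix$values
  with_seed(seed, {
    pct <- 100 * stats::plogis(link_slope * (v - link_midpoint))
    if (noise_sd_percent > 0)
      pct <- pct + stats::rnorm(length(pct), 0, noise_sd_percent)
    pct <- pmin(100, pmax(0, pct))
    data.frame(locus_id = rep(rownames(v), ncol(v)),
               sample_id = rep(colnames(v), each = nrow(v)),
               percent = as.vector(pct), stringsAsFactors = FALSE)
  })
}
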