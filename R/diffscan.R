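# The differential-methylation scan: per-locus paired t-tests across matched
# case/control pairs, methylation-state calls at the zero-ratio threshold, a
# permutation null for threshold calibration, and a fold-change-weighted
# ranking statistic used for ordering only.

#' Call methylation state from a log2(HpaII/MspI) ratio
#'
#' Ratios below zero indicate methylation (HpaII fails to cut), above zero
#' hypomethylation. Exactly zero is called `boundary` and excluded from
#' state-change summaries; states are defined by strict inequalities only.
#'
#' @param ratio numeric vector of log2 ratios.
#' @return character vector: `"methylated"`, `"hypomethylated"`,
#'   `"boundary"`, or `NA` for missing input.
#' @examples
#' call_state(c(2.06, -1.29, 0))
#' @export
call_state <- function(ratio) {
  out <- rep(NA_character_, length(ratio))
  out[!is.na(ratio) & ratio < 0] <- "methylated"
  out[!is.na(ratio) & ratio > 0] <- "hypomethylated"
  out[!is.na(ratio) & ratio == 0] <- "boundary"
  out
}

# Split matrix columns into case/control blocks ordered by pair.
# Returns list(case, control) of column matrices aligned pairwise.
pair_columns <- function(x, samples) {
  samples <- validate_sample_table(samples)
  missing <- setdiff(samples$sample_id, colnames(x$values))
  if (length(missing))
    stop("sample(s) absent from matrix: ", paste(missing, collapse = ", "))
  pairs <- sort(unique(samples$pair_id))
  case_ids <- samples$sample_id[match(paste(pairs, "case"),
                                      paste(samples$pair_id, samples$group))]
  ctrl_ids <- samples$sample_id[match(paste(pairs, "control"),
                                      paste(samples$pair_id, samples$group))]
  list(case = x$values[, case_ids, drop = FALSE],
       control = x$values[, ctrl_ids, drop = FALSE],
       pairs = pairs)
}

# Row-wise paired t on a matrix of within-pair differences (rows = loci).
# Returns data.frame(mean_diff, sd_diff, n_used, t, p, degenerate).
row_paired_t <- function(D) {
  n_used <- rowSums(!is.na(D))
  mean_d <- rowMeans(D, na.rm = TRUE)
  sd_d <- sqrt(pmax(0, rowSums((D - mean_d)^2, na.rm = TRUE)) /
                 pmax(1, n_used - 1))
  tstat <- mean_d / (sd_d / sqrt(n_used))
  p <- 2 * stats::pt(-abs(tstat), df = n_used - 1)
  # all-zero differences carry no evidence: t = 0, p = 1; zero spread around
  # a nonzero mean leaves the t distribution undefined, so p stays missing
  zero_all <- n_used >= 2 & sd_d == 0 & mean_d == 0
  tstat[zero_all] <- 0
  p[zero_all] <- 1
  degenerate <- n_used >= 2 & sd_d == 0 & mean_d != 0
  bad <- n_used < 2 | degenerate
  tstat[bad] <- NA_real_
  p[bad] <- NA_real_
  mean_d[n_used == 0] <- NA_real_
  data.frame(mean_diff = mean_d, sd_diff = sd_d, n_used = n_used,
             t = tstat, p = p, degenerate = degenerate)
}

#' Per-locus paired t-test scan
#'
#' For every locus, within-pair differences (case minus matched control) are
#' tested against zero: `t = mean(d) / (sd(d) / sqrt(k))` over the `k`
#' complete pairs, with a two-sided p-value from the t distribution on `k-1`
#' degrees of freedom. Group means, the case-minus-control difference and
#' methylation-state calls are reported alongside. Loci with fewer than two
#' complete pairs get missing `t`/`p`. Zero paired-difference variance
#' around a nonzero mean leaves the t distribution undefined: such loci get
#' missing `t`/`p` and the `degenerate` flag (a literal p of 0 is never
#' emitted), while all-zero differences yield `t = 0`, `p = 1`.
#'
#' @param x a `MethylationMatrix`.
#' @param samples sample sheet with matched `pair_id`s
#'   (see [validate_sample_table()]).
#' @return A `LocusStats` data.frame: one row per locus with coordinates,
#'   `mean_case`, `mean_control`, `difference`, `sd_paired_diff`,
#'   `n_pairs_used`, `t`, `p`, `state_case`, `state_control`, `degenerate`.
#' @export
paired_t_scan <- function(x, samples) {
  stopifnot(inherits(x, "MethylationMatrix"))
  pc <- pair_columns(x, samples)
  D <- pc$case - pc$control
  tt <- row_paired_t(D)
  mean_case <- rowMeans(pc$case, na.rm = TRUE)
  mean_control <- rowMeans(pc$control, na.rm = TRUE)
  out <- data.frame(x$loci[, c("locus_id", "chrom", "start", "end")],
                    mean_case = mean_case, mean_control = mean_control,
                    difference = mean_case - mean_control,
                    sd_paired_diff = tt$sd_diff,
                    n_pairs_used = tt$n_used,
                    t = tt$t, p = tt$p,
                    state_case = call_state(mean_case),
                    state_control = call_state(mean_control),
                    degenerate = tt$degenerate,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("LocusStats", "data.frame")
  out
}

#' Ranking configuration for the fold-change-weighted statistic
#'
#' @param s0 non-negative stabilization constant (log2 units) added to the
#'   paired-difference SD in the denominator; `NULL` (default) means the
#'   median `sd_paired_diff` across loci, the usual SAM-style choice that
#'   keeps small-variance loci from dominating.
#' @param variant formula variant tag; `"sam"` is the canonical
#'   fold-change-weighted form `|mean paired difference| / (sd + s0)`.
#' @return A `RankingConfig` list.
#' @export
ranking_config <- function(s0 = NULL, variant = "sam") {
  if (!is.null(s0) && s0 < 0) stop("s0 must be >= 0")
  structure(list(s0 = s0, variant = match.arg(variant, "sam")),
            class = "RankingConfig")
}

#' Fold-change-weighted rank scores
#'
#' Scores each locus by `|mean paired difference| / (sd_paired_diff + s0)`.
#' Relative to the plain t statistic this weights the mean shift
#' (fold-change on the log scale) more heavily than the within-group
#' variability. Scores are used exclusively to rank loci; they are never
#' interpreted as probabilities.
#'
#' @param x a `MethylationMatrix`.
#' @param samples sample sheet.
#' @param config a [ranking_config()].
#' @return Named numeric vector of scores (names = locus IDs), `Inf` where
#'   both the SD and `s0` are zero (such loci rank first; a warning is
#'   emitted).
#' @export
rank_scores <- function(x, samples, config = ranking_config()) {
  pc <- pair_columns(x, samples)
  tt <- row_paired_t(pc$case - pc$control)
  s0 <- config$s0
  if (is.null(s0)) s0 <- stats::median(tt$sd_diff, na.rm = TRUE)
  denom <- tt$sd_diff + s0
  score <- abs(tt$mean_diff) / denom
  if (any(denom == 0, na.rm = TRUE)) {
    warning(sum(denom == 0, na.rm = TRUE),
            " loci with zero spread and s0 = 0: score set to Inf, ranked first")
    score[denom == 0] <- Inf
  }
  stats::setNames(score, x$loci$locus_id)
}

#' Permutation null distribution for the scan
#'
#' Re-runs the per-locus test under relabelled data. Two schemes:
#' `within_pair_flip` (default) swaps case/control labels independently
#' within each pair, respecting the matched design the paired t-test
#' assumes; when the number of pairs `k` gives `2^k <= n_perm`, all
#' `2^k - 1` non-identity sign patterns are enumerated exhaustively.
#' `full_relabel` shuffles group labels across all samples preserving group
#' sizes and applies an unpaired equal-variance t-test per locus.
#'
#' Per-locus permutation p-values count the identity labelling as one
#' permutation, so they equal the fraction of all sign patterns (including
#' identity) whose |t| reaches the observed |t|.
#'
#' @param x a `MethylationMatrix`.
#' @param samples sample sheet.
#' @param n_perm number of permutations (>= 1).
#' @param scheme `"within_pair_flip"` or `"full_relabel"`.
#' @param seed integer seed for sampled permutations.
#' @return A `PermutationNull` list: `scheme`, `seed`, `n_perm` (stored
#'   permutations), `exhaustive`, `min_p` (per-permutation minimum p),
#'   `perm_p` (per-locus permutation p), and `p_matrix` (loci x
#'   permutations) when small enough to keep.
#' @export
permutation_null <- function(x, samples, n_perm = 100,
                             scheme = c("within_pair_flip", "full_relabel"),
                             seed = 1L) {
  scheme <- match.arg(scheme)
  if (n_perm < 1) stop("n_perm must be >= 1")
  pc <- pair_columns(x, samples)
  k <- length(pc$pairs)
  obs_t <- if (scheme == "within_pair_flip")
    row_paired_t(pc$case - pc$control)$t
  else
    row_unpaired_t(cbind(pc$case, pc$control),
                   rep(c(TRUE, FALSE), c(k, k)))$t

  with_seed(seed, {
    if (scheme == "within_pair_flip") {
      exhaustive <- 2^k <= n_perm
      if (exhaustive && k > 20)
        stop("exhaustive enumeration over ", k,
             " pairs is infeasible; use sampled permutations (smaller n_perm)")
      D <- pc$case - pc$control
      if (exhaustive) {
        signs <- as.matrix(expand.grid(rep(list(c(1, -1)), k)))
        signs <- signs[rowSums(signs == 1) != k, , drop = FALSE]  # drop identity
      } else {
        signs <- matrix(sample(c(1, -1), n_perm * k, replace = TRUE),
                        nrow = n_perm)
      }
      n_stored <- nrow(signs)
      keep_matrix <- nrow(D) * n_stored <= 5e6
      min_p <- numeric(n_stored)
      exceed <- numeric(nrow(D))
      p_matrix <- if (keep_matrix)
        matrix(NA_real_, nrow(D), n_stored,
               dimnames = list(x$loci$locus_id, NULL)) else NULL
      for (j in seq_len(n_stored)) {
        tt <- row_paired_t(sweep(D, 2, signs[j, ], `*`))
        min_p[j] <- suppressWarnings(min(tt$p, na.rm = TRUE))
        exceed <- exceed + as.numeric(!is.na(tt$t) & !is.na(obs_t) &
                                        abs(tt$t) >= abs(obs_t))
        if (keep_matrix) p_matrix[, j] <- tt$p
      }
      denom <- if (exhaustive) 2^k else n_stored + 1
      perm_p <- (exceed + 1) / denom    # identity labelling counts once
    } else {
      n_samp <- 2 * k
      vals <- cbind(pc$case, pc$control)
      n_stored <- n_perm
      keep_matrix <- nrow(vals) * n_stored <= 5e6
      min_p <- numeric(n_stored)
      exceed <- numeric(nrow(vals))
      p_matrix <- if (keep_matrix)
        matrix(NA_real_, nrow(vals), n_stored,
               dimnames = list(x$loci$locus_id, NULL)) else NULL
      for (j in seq_len(n_stored)) {
        grp <- rep(FALSE, n_samp)
        grp[sample(n_samp, k)] <- TRUE
        tt <- row_unpaired_t(vals, grp)
        min_p[j] <- suppressWarnings(min(tt$p, na.rm = TRUE))
        exceed <- exceed + as.numeric(!is.na(tt$t) & !is.na(obs_t) &
                                        abs(tt$t) >= abs(obs_t))
        if (keep_matrix) p_matrix[, j] <- tt$p
      }
      perm_p <- (exceed + 1) / (n_stored + 1)
      exhaustive <- FALSE
    }
    structure(list(scheme = scheme, seed = seed, n_perm = n_stored,
                   exhaustive = exhaustive, min_p = min_p,
                   perm_p = stats::setNames(perm_p, x$loci$locus_id),
                   p_matrix = p_matrix),
              class = "PermutationNull")
  })
}

# Row-wise unpaired equal-variance t-test; grp is logical (TRUE = case).
row_unpaired_t <- function(vals, grp) {
  a <- vals[, grp, drop = FALSE]
  b <- vals[, !grp, drop = FALSE]
  na_ <- rowSums(!is.na(a)); nb <- rowSums(!is.na(b))
  ma <- rowMeans(a, na.rm = TRUE); mb <- rowMeans(b, na.rm = TRUE)
  ssa <- rowSums((a - ma)^2, na.rm = TRUE)
  ssb <- rowSums((b - mb)^2, na.rm = TRUE)
  df <- na_ + nb - 2
  sp2 <- (ssa + ssb) / pmax(1, df)
  tstat <- (ma - mb) / sqrt(sp2 * (1 / na_ + 1 / nb))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  bad <- na_ < 2 | nb < 2 | sp2 == 0
  tstat[bad] <- NA_real_; p[bad] <- NA_real_
  data.frame(t = tstat, p = p)
}

#' Permutation-calibrated significance threshold
#'
#' Formalizes the rule "no test statistic under any permutation reached a
#' p-value this low": the threshold is the largest round value, from the
#' fixed ladder `{5e-1, 1e-1, 5e-2, 1e-2, ...}`, strictly below the minimum
#' p-value observed across all permutations.
#'
#' @param null a `PermutationNull`.
#' @return list with `alpha_star` (the chosen threshold) and
#'   `permutation_min_p` (the observed permutation floor, verbatim).
#' @examples
#' sig <- structure(list(min_p = 1.5e-5), class = "PermutationNull")
#' significance_threshold(sig)$alpha_star  # 1e-5
#' @export
significance_threshold <- function(null) {
  if (is.null(null$min_p) || !length(null$min_p))
    stop("empty permutation null")
  floor_p <- min(null$min_p, na.rm = TRUE)
  ladder <- sort(c(10^-(1:30), 5 * 10^-(1:30)), decreasing = TRUE)
  below <- ladder[ladder < floor_p]
  if (!length(below))
    stop("permutation minimum p below the threshold ladder (", floor_p, ")")
  list(alpha_star = below[1], permutation_min_p = floor_p)
}

#' Select candidate loci in two significance tiers
#'
#' Splits the scan into a significant tier (`p < alpha_star`) and a moderate
#' tier (`alpha_star <= p < moderate_alpha`), plus p-value histogram counts
#' over fixed bins for null-versus-observed distribution plots. Candidates
#' are sorted by p, ties broken by |difference| (largest first).
#'
#' @param stats a `LocusStats` data.frame from [paired_t_scan()].
#' @param alpha_star significant-tier threshold.
#' @param moderate_alpha moderate-tier threshold; must exceed `alpha_star`.
#' @param bin_width histogram bin width on `[0, 1]` (default 0.01).
#' @return list with `significant`, `moderate` (LocusStats subsets) and
#'   `histogram` (`bin_start`, `bin_end`, `count`).
#' @export
select_candidates <- function(stats, alpha_star, moderate_alpha = 10 * alpha_star,
                              bin_width = 0.01) {
  if (moderate_alpha <= alpha_star)
    stop("moderate_alpha must exceed alpha_star")
  p <- stats$p
  ord <- order(p, -abs(stats$difference))
  sorted <- stats[ord, , drop = FALSE]
  sig <- sorted[!is.na(sorted$p) & sorted$p < alpha_star, , drop = FALSE]
  mod <- sorted[!is.na(sorted$p) & sorted$p >= alpha_star &
                  sorted$p < moderate_alpha, , drop = FALSE]
  breaks <- seq(0, 1, by = bin_width)
  counts <- graphics::hist(p[!is.na(p)], breaks = breaks, plot = FALSE)$counts
  list(significant = sig, moderate = mod,
       histogram = data.frame(bin_start = utils::head(breaks, -1),
                              bin_end = breaks[-1], count = counts))
}
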