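# Cross-platform validation: array log-ratios vs bisulphite percent
# methylation (expected strongly negative correlation: high ratio =
# hypomethylated = low percent), and site-level group difference tests on
# percent-methylation values.

#' Cross-platform concordance of log-ratios and percent methylation
#'
#' Pearson correlation across loci between the array log2 ratio and the
#' bisulphite percent methylation, plus residuals from the least-squares
#' line. Since the two scales run in opposite directions, a concordant
#' pair of platforms yields a strongly negative R.
#'
#' @param ratio numeric vector of per-locus log2 ratios.
#' @param percent numeric vector of matched percent-methylation values.
#' @param locus_id optional locus labels for the residual table.
#' @return list: `r` (Pearson correlation), `slope`, `intercept`,
#'   `residuals` (data.frame per locus).
#' @export
platform_concordance <- function(ratio, percent, locus_id = NULL) {
  ok <- !is.na(ratio) & !is.na(percent)
  ratio <- ratio[ok]; percent <- percent[ok]
  if (is.null(locus_id)) locus_id <- paste0("locus_", seq_along(ratio))
  else locus_id <- locus_id[ok]
  if (length(ratio) < 3) stop("need >= 3 loci with both measurements")
  if (stats::sd(ratio) == 0 || stats::sd(percent) == 0)
    stop("zero variance on one axis: correlation undefined")
  fit <- stats::lm(percent ~ ratio)
  list(r = stats::cor(ratio, percent),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       residuals = data.frame(locus_id = locus_id, ratio = ratio,
                              percent = percent,
                              residual = unname(stats::residuals(fit)),
                              stringsAsFactors = FALSE))
}

#' Site-level group difference in percent methylation
#'
#' Difference of group means in percentage points with a two-sided p-value
#' from the unpaired equal-variance t-test (default) or the exact
#' Mann-Whitney test.
#'
#' @param case_percents,control_percents numeric vectors (>= 2 values each).
#' @param method `"t"` (default) or `"wilcoxon"`; `"both"` reports both
#'   p-values.
#' @return list: `difference` (mean case - mean control), `p`, `method`,
#'   and `p_wilcoxon` when `method = "both"`.
#' @export
site_difference_test <- function(case_percents, control_percents,
                                 method = c("t", "wilcoxon", "both")) {
  method <- match.arg(method)
  if (length(case_percents) < 2 || length(control_percents) < 2)
    stop("need >= 2 values per group")
  diff <- mean(case_percents) - mean(control_percents)
  all_equal <- stats::sd(c(case_percents, control_percents)) == 0
  # two constant but unequal groups leave the t statistic undefined
  degenerate <- !all_equal && stats::sd(case_percents) == 0 &&
    stats::sd(control_percents) == 0
  p_t <- if (all_equal) 1
  else if (degenerate) {
    warning("zero within-group variance: t-test p undefined")
    NA_real_
  } else stats::t.test(case_percents, control_percents,
                       var.equal = TRUE)$p.value
  if (method == "t") return(list(difference = diff, p = p_t, method = "t"))
  p_w <- if (all_equal) 1 else
    suppressWarnings(stats::wilcox.test(case_percents, control_percents,
                                        exact = TRUE)$p.value)
  if (method == "wilcoxon")
    list(difference = diff, p = p_w, method = "wilcoxon")
  else
    list(difference = diff, p = p_t, p_wilcoxon = p_w, method = "both")
}
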