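# Shared in-code fixtures and independent oracles.

# Build a MethylationMatrix from a plain value matrix, inventing well-spaced
# chr1 coordinates; colnames are required, rownames optional.
toy_matrix <- function(values, chrom = "chr1") {
  values <- as.matrix(values)
  n <- nrow(values)
  start <- seq_len(n) * 10000
  rownames(values) <- sprintf("%s:%d-%d", chrom, start + 1, start + 100)
  methylation_matrix(values)
}

# Matched sample sheet for k pairs with column names case_01.. / control_01..
toy_samples <- function(k) {
  data.frame(
    sample_id = c(sprintf("case_%02d", 1:k), sprintf("control_%02d", 1:k)),
    group = rep(c("case", "control"), each = k),
    pair_id = rep(sprintf("P%02d", 1:k), 2),
    gender = "F", ethnicity = "none",
    stringsAsFactors = FALSE
  )
}

# Matrix with k case and k control columns built from a loci x k matrix of
# control values and a matrix of within-pair differences.
toy_paired_matrix <- function(control_vals, pair_diffs) {
  k <- ncol(control_vals)
  vals <- cbind(control_vals + pair_diffs, control_vals)
  colnames(vals) <- c(sprintf("case_%02d", 1:k), sprintf("control_%02d", 1:k))
  toy_matrix(vals)
}

# Closed-form paired t-test oracle, independent of the scan implementation:
# t from first principles, p through the regularized incomplete beta
# function (the t-distribution tail identity), not through pt().
oracle_paired_t <- function(d) {
  k <- length(d)
  tstat <- mean(d) / (stats::sd(d) / sqrt(k))
  df <- k - 1
  p <- stats::pbeta(df / (df + tstat^2), df / 2, 0.5)
  list(t = tstat, p = p)
}

# Quantile-normalization oracle: sort each column, average order statistics,
# reassign by rank. Assumes no ties and no missing values.
oracle_quantile_normalize <- function(m) {
  target <- rowMeans(apply(m, 2, sort))
  apply(m, 2, function(col) target[rank(col)])
}

# Right-tail hypergeometric oracle by explicit binomial-coefficient
# summation.
oracle_hyper_tail <- function(overlap, list_size, set_size, universe) {
  xs <- overlap:min(list_size, set_size)
  sum(choose(set_size, xs) * choose(universe - set_size, list_size - xs)) /
    choose(universe, list_size)
}

# Brute-force interval overlap (half-open): any pair with >= 1 shared base.
oracle_overlaps <- function(loci, track_iv) {
  vapply(seq_len(nrow(loci)), function(i) {
    any(track_iv$chrom == loci$chrom[i] &
          track_iv$start < loci$end[i] &
          track_iv$end > loci$start[i])
  }, logical(1))
}
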