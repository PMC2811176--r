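# Normalization and sample-level QC for log-ratio matrices.

#' Quantile-normalize a ratio matrix
#'
#' Forces every sample's empirical distribution to the across-sample mean of
#' order statistics while preserving within-sample rank order; tied input
#' values receive the mean of their would-be target quantiles. Loci with any
#' missing value are dropped first (count reported via a message), since the
#' normalization is defined on complete rows.
#'
#' @param x a `MethylationMatrix`.
#' @return A `MethylationMatrix` of the complete loci, normalized. A
#'   single-sample matrix is returned unchanged with a warning.
#' @examples
#' m <- matrix(c(1, 2, 3, 2, 4, 6), 3, 2,
#'             dimnames = list(paste0("chr1:", c(1, 101, 201), "-",
#'                                    c(50, 150, 250)), c("a", "b")))
#' quantile_normalize(methylation_matrix(m))$values  # both columns 1.5, 3, 4.5
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "MethylationMatrix"))
  if (ncol(x$values) < 2) {
    warning("single-sample matrix: quantile normalization is a no-op")
    return(x)
  }
  keep <- stats::complete.cases(x$values)
  if (!all(keep))
    message(sum(!keep), " loci with missing values dropped before quantile normalization")
  v <- x$values[keep, , drop = FALSE]
  vn <- limma::normalizeQuantiles(v, ties = TRUE)
  dimnames(vn) <- dimnames(v)
  methylation_matrix(vn, x$loci[keep, , drop = FALSE])
}

#' Median-center each array
#'
#' Subtracts the per-sample median, so relative differences within a sample
#' are unchanged; idempotent.
#'
#' @param x a `MethylationMatrix`.
#' @return Centered `MethylationMatrix`.
#' @export
center_arrays <- function(x) {
  stopifnot(inherits(x, "MethylationMatrix"))
  med <- apply(x$values, 2, stats::median, na.rm = TRUE)
  methylation_matrix(sweep(x$values, 2, med), x$loci)
}

#' Pairwise inter-sample Pearson correlations
#'
#' For each pair of samples, the Pearson correlation over loci with no
#' missing value in either sample. A consistent cohort shows a tight high
#' band of correlations; outlying samples stand out.
#'
#' @param x a `MethylationMatrix` with >= 2 samples and >= 3 loci.
#' @return Symmetric correlation matrix, unit diagonal; `NA` where a sample
#'   has zero variance on the shared loci.
#' @export
pairwise_pearson <- function(x) {
  stopifnot(inherits(x, "MethylationMatrix"))
  if (ncol(x$values) < 2) stop("need >= 2 samples")
  if (nrow(x$values) < 3) stop("need >= 3 loci")
  suppressWarnings(stats::cor(x$values, use = "pairwise.complete.obs",
                              method = "pearson"))
}

#' Ward hierarchical clustering of samples
#'
#' Agglomerates sample columns under Ward's minimum-variance criterion on
#' Euclidean distances (the `ward.D2` linkage, which operates on the
#' distances themselves rather than their squares). Loci with missing
#' values are excluded.
#'
#' @param x a `MethylationMatrix` with >= 2 samples.
#' @return An object of class `hclust`.
#' @export
ward_cluster <- function(x) {
  stopifnot(inherits(x, "MethylationMatrix"))
  if (ncol(x$values) < 2) stop("need >= 2 samples")
  v <- x$values[stats::complete.cases(x$values), , drop = FALSE]
  stats::hclust(stats::dist(t(v), method = "euclidean"), method = "ward.D2")
}

#' Write a sample dendrogram in Newick format
#'
#' @param hc an `hclust` tree from [ward_cluster()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Matrix quality-control summary
#'
#' Missingness per sample, per-sample distribution summaries and the
#' pairwise correlation table, as a lightweight QC report.
#'
#' @param x a `MethylationMatrix`.
#' @return list with `missingness` (per-sample NA counts), `summary`
#'   (per-sample quartiles), `correlations` (from [pairwise_pearson()]).
#' @export
qc_report <- function(x) {
  stopifnot(inherits(x, "MethylationMatrix"))
  v <- x$values
  miss <- colSums(is.na(v))
  qs <- t(apply(v, 2, stats::quantile, probs = c(0, .25, .5, .75, 1),
                na.rm = TRUE))
  list(missingness = miss, summary = qs, correlations = pairwise_pearson(x))
}
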