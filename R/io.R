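#' Construct a MethylationMatrix
#'
#' The central container: a loci x samples matrix of log2(HpaII/MspI) ratios
#' with genomic coordinates per locus. High ratios indicate hypomethylation
#' (the methylation-sensitive HpaII cut), low ratios methylation.
#'
#' @param values numeric matrix, rows = loci, columns = samples. Row and
#'   column names are required and must be unique.
#' @param loci data.frame with columns `locus_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `strand`, one row per matrix row. If
#'   `NULL`, coordinates are parsed from the rownames of `values` as
#'   `"chrom:start-end"` keys.
#' @return An object of class `MethylationMatrix`: a list with elements
#'   `values` and `loci`.
#' @examples
#' m <- matrix(c(0, 1), 1, 2, dimnames = list("chr1:11-20", c("s1", "s2")))
#' mm <- methylation_matrix(m)
#' mm$loci$start  # 10: printed keys are 1-based inclusive, internal half-open
#' @export
methylation_matrix <- function(values, loci = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have locus rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate locus ID: ", rownames(values)[duplicated(rownames(values))][1])
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ID: ", colnames(values)[duplicated(colnames(values))][1])
  if (is.null(loci)) {
    loci <- parse_locus_keys(rownames(values))
  } else {
    if (nrow(loci) != nrow(values) || !identical(loci$locus_id, rownames(values)))
      stop("loci table does not match matrix rows")
  }
  validate_intervals(loci, "locus")
  bad <- is.infinite(values)
  if (any(bad, na.rm = TRUE)) stop("non-finite (infinite) ratio values present")
  structure(list(values = values, loci = loci), class = "MethylationMatrix")
}

#' @export
print.MethylationMatrix <- function(x, ...) {
  cat(sprintf("MethylationMatrix: %d loci x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  missing values: %d\n", sum(is.na(x$values))))
  cat("  samples:", paste(utils::head(colnames(x$values), 8), collapse = ", "),
      if (ncol(x$values) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.MethylationMatrix <- function(x) dim(x$values)

#' Read a log-ratio matrix from TSV
#'
#' Expects a header row of sample IDs and a first column of locus keys in
#' 1-based inclusive `"chrom:start-end"` form. Missing values are encoded as
#' `NA`. Coordinates are converted to the internal 0-based half-open
#' convention; row and column order is preserved.
#'
#' @param path path to a tab-delimited file.
#' @return A [methylation_matrix()].
#' @export
read_ratio_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                          colClasses = list(character = 1), data.table = FALSE)
  if (ncol(dt) < 2) stop("ratio matrix must have a key column and >= 1 sample")
  keys <- dt[[1]]
  dup <- duplicated(keys)
  if (any(dup)) stop("duplicate locus key: ", keys[dup][1])
  vals <- dt[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(!is.na(col) & is.na(suppressWarnings(as.numeric(col))))
      if (length(bad))
        stop(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                     bad[1], names(vals)[j], col[bad[1]]))
      vals[[j]] <- as.numeric(col)
    }
  }
  values <- as.matrix(vals)
  rownames(values) <- keys
  methylation_matrix(values)
}

#' Write a log-ratio matrix to TSV
#'
#' Inverse of [read_ratio_matrix()]: locus keys are serialized back to their
#' 1-based inclusive printed form, missing values as `NA`. Read-after-write
#' reproduces the matrix exactly at the printed precision.
#'
#' @param x a `MethylationMatrix`.
#' @param path output path.
#' @param digits significant digits for values (default 10, ample for log2
#'   ratio data).
#' @return `path`, invisibly.
#' @export
write_ratio_matrix <- function(x, path, digits = 10) {
  stopifnot(inherits(x, "MethylationMatrix"))
  keys <- format_locus_keys(x$loci$chrom, x$loci$start, x$loci$end)
  out <- data.frame(locus = keys,
                    signif(x$values, digits),
                    check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read an annotation track from BED
#'
#' BED is 0-based half-open, matching the internal convention, so intervals
#' are loaded verbatim. Only the first three columns are used; a fourth
#' column, when present, is kept as interval name.
#'
#' @param path path to a BED3+ file.
#' @param feature_kind one of `"CpG_island"`, `"CG_cluster"`, `"conserved"`,
#'   `"repeat_RT"`, `"repeat_LT"`, `"other"`.
#' @param name track name; defaults to the file base name.
#' @return An `AnnotationTrack`: list with `name`, `feature_kind` and an
#'   `intervals` data.frame (`chrom`, `start`, `end`, `strand`).
#' @export
read_intervals <- function(path, feature_kind = "other", name = NULL) {
  feature_kind <- match.arg(feature_kind, .feature_kinds)
  if (is.null(name)) name <- sub("\\.bed$", "", basename(path))
  if (file.size(path) == 0) {
    return(annotation_track(name, feature_kind,
                            data.frame(chrom = character(), start = numeric(),
                                       end = numeric(), strand = character())))
  }
  dt <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE)
  if (ncol(dt) < 3) stop("BED file needs >= 3 columns: ", path)
  iv <- data.frame(chrom = as.character(dt[[1]]),
                   start = as.numeric(dt[[2]]), end = as.numeric(dt[[3]]),
                   strand = "*", stringsAsFactors = FALSE)
  bad <- which(iv$start >= iv$end)
  if (length(bad)) stop("invalid BED interval (start >= end) at line ", bad[1])
  annotation_track(name, feature_kind, iv)
}

.feature_kinds <- c("CpG_island", "CG_cluster", "conserved",
                    "repeat_RT", "repeat_LT", "other")

#' Construct an annotation track
#'
#' @param name track name.
#' @param feature_kind feature class, from the closed set used in candidate
#'   reports (CpG islands, CG clusters, conserved elements, repeat classes).
#' @param intervals data.frame of 0-based half-open intervals.
#' @return An `AnnotationTrack` object.
#' @export
annotation_track <- function(name, feature_kind, intervals) {
  feature_kind <- match.arg(feature_kind, .feature_kinds)
  if (nrow(intervals)) validate_intervals(intervals, paste0("track '", name, "'"))
  structure(list(name = name, feature_kind = feature_kind,
                 intervals = intervals), class = "AnnotationTrack")
}

#' Write an annotation track as BED3
#' @param track an `AnnotationTrack`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(track, path) {
  iv <- track$intervals
  data.table::fwrite(iv[, c("chrom", "start", "end")], path, sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or validate a sample sheet
#'
#' The sample sheet encodes the matched design: columns `sample_id`, `group`
#' (`case`/`control`), `pair_id`, `gender` (`M`/`F`), `ethnicity`. Every
#' `pair_id` must occur exactly twice, once per group.
#'
#' @param path path to a tab-delimited sample sheet.
#' @return A validated data.frame.
#' @export
read_sample_table <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = "character")
  validate_sample_table(df)
}

#' @rdname read_sample_table
#' @param df a data.frame to validate in place.
#' @export
validate_sample_table <- function(df) {
  need <- c("sample_id", "group", "pair_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][1])
  if (!all(df$group %in% c("case", "control")))
    stop("group must be 'case' or 'control'")
  tab <- table(df$pair_id, df$group)
  if (!all(tab == 1L))
    stop("every pair_id must occur exactly twice, once per group; offending pair: ",
         rownames(tab)[which(tab != 1L, arr.ind = TRUE)[1, 1]])
  df
}

#' Write a sample sheet
#' @param df sample table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read gene models from a 6-column TSV
#'
#' Columns: gene symbol, transcript ID, chrom, start, end (0-based
#' half-open gene body), strand. The transcription start site is derived
#' from strand: body start on `+`, body end - 1 on `-`.
#'
#' @param path path to the TSV (header required:
#'   `symbol transcript chrom start end strand`).
#' @return A data.frame with the six columns plus derived `tss`.
#' @export
read_gene_models <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("symbol", "transcript", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene model table missing column(s): ",
                         paste(miss, collapse = ", "))
  gene_models(df)
}

#' @rdname read_gene_models
#' @param df data.frame with columns `symbol`, `transcript`, `chrom`,
#'   `start`, `end`, `strand`.
#' @export
gene_models <- function(df) {
  if (!all(df$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  validate_intervals(df, "gene body")
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  df
}

#' Write gene models to TSV
#' @param genes gene model data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  cols <- c("symbol", "transcript", "chrom", "start", "end", "strand")
  data.table::fwrite(genes[, cols], path, sep = "\t", quote = FALSE)
  invisible(path)
}
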