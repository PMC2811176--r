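#' Parse locus keys of the form "chrom:start-end"
#'
#' Locus keys as printed in candidate tables are 1-based with inclusive ends
#' (UCSC browser style). Internally all coordinates are 0-based half-open,
#' matching BED, so a printed key `"chr2:235526053-235526128"` becomes the
#' interval `[235526052, 235526128)`.
#'
#' @param keys character vector of `"chrom:start-end"` keys (1-based inclusive).
#' @return A data.frame with columns `locus_id` (the original key), `chrom`,
#'   `start`, `end` (0-based half-open) and `strand` (`"*"`; locus keys carry
#'   no strand).
#' @examples
#' parse_locus_keys("chr2:235526053-235526128")
#' @export
parse_locus_keys <- function(keys) {
  keys <- as.character(keys)
  m <- regmatches(keys, regexec("^([^:]+):([0-9]+)-([0-9]+)$", keys))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop("malformed locus key(s): ", paste(utils::head(keys[bad], 5), collapse = ", "))
  }
  chrom <- vapply(m, `[`, character(1), 2L)
  start1 <- as.numeric(vapply(m, `[`, character(1), 3L))
  end1 <- as.numeric(vapply(m, `[`, character(1), 4L))
  if (any(start1 > end1)) {
    stop("locus key with start > end: ",
         paste(keys[start1 > end1][1], collapse = ", "))
  }
  data.frame(locus_id = keys, chrom = chrom, start = start1 - 1, end = end1,
             strand = "*", stringsAsFactors = FALSE)
}

#' Format internal intervals back to printed locus keys
#'
#' Inverse of [parse_locus_keys()]: 0-based half-open `[start, end)` is
#' rendered as 1-based inclusive `"chrom:start+1-end"`.
#'
#' @param chrom,start,end vectors describing 0-based half-open intervals.
#' @return Character vector of keys.
#' @export
format_locus_keys <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, as.integer(start) + 1L, as.integer(end))
}

#' Validate a set of genomic intervals
#'
#' Intervals are 0-based half-open; `start < end` and non-empty `chrom` are
#' required.
#'
#' @param df data.frame with columns `chrom`, `start`, `end`.
#' @param context label used in error messages.
#' @return `df`, invisibly, if valid.
#' @keywords internal
validate_intervals <- function(df, context = "interval") {
  if (any(is.na(df$chrom) | !nzchar(df$chrom)))
    stop(context, ": empty chromosome name")
  bad <- which(!(df$start < df$end))
  if (length(bad))
    stop(context, ": start >= end at row ", bad[1])
  invisible(df)
}

#' Convert interval columns to a GRanges object
#'
#' Internal 0-based half-open intervals map to the 1-based closed convention
#' of `GRanges` by shifting start up by one.
#'
#' @param df data.frame with `chrom`, `start`, `end` and optionally `strand`.
#' @return A [GenomicRanges::GRanges] object, names taken from `locus_id`
#'   when present.
#' @export
as_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
  if ("locus_id" %in% names(df)) names(gr) <- df$locus_id
  gr
}
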