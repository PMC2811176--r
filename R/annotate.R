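# Annotation of candidate loci: feature-track overlap flags, strand-aware
# promoter/gene-body assignment, hypergeometric enrichment scoring, and the
# candidate-table report builder.

#' Overlap flags between loci and annotation tracks
#'
#' One boolean per (locus, track): `TRUE` iff the locus interval intersects
#' at least one track interval by >= 1 bp (half-open intersection; abutting
#' intervals do not overlap). Chromosomes present in the loci but absent
#' from a track simply yield `FALSE`.
#'
#' @param loci data.frame of loci (`locus_id`, `chrom`, `start`, `end`) or a
#'   `MethylationMatrix`.
#' @param tracks list of `AnnotationTrack` objects (see [read_intervals()]).
#' @return data.frame: `locus_id` plus one logical column per track (named
#'   by track name).
#' @export
overlap_flags <- function(loci, tracks) {
  if (inherits(loci, "MethylationMatrix")) loci <- loci$loci
  gr <- as_granges(loci)
  out <- data.frame(locus_id = loci$locus_id, stringsAsFactors = FALSE)
  for (tr in tracks) {
    if (nrow(tr$intervals)) {
      absent <- setdiff(unique(loci$chrom), unique(tr$intervals$chrom))
      if (length(absent))
        message("track '", tr$name, "': no intervals on ",
                length(absent), " locus chromosome(s); flags there are FALSE")
      hits <- suppressWarnings(GenomicRanges::countOverlaps(
        gr, as_granges(tr$intervals), minoverlap = 1L, ignore.strand = TRUE))
      out[[tr$name]] <- hits > 0
    } else {
      out[[tr$name]] <- rep(FALSE, nrow(loci))
    }
  }
  out
}

#' Assign loci to genes: promoter, gene body, bidirectional promoter
#'
#' A locus is promoter-assigned (PRO) to a gene when it intersects the
#' strand-aware window covering the 10 kb (by default) upstream of the
#' transcription start site — `[TSS - w, TSS)` on the `+` strand, mirrored
#' on `-` — and gene-body-assigned (GB) when it intersects the gene body.
#' GB takes precedence over PRO for the same gene; a locus that is PRO for
#' two or more genes on opposite strands and GB for none is a bidirectional
#' promoter (PRO2). Loci matching nothing get category `none`.
#'
#' @param loci data.frame of loci or a `MethylationMatrix`.
#' @param genes gene model data.frame from [read_gene_models()] /
#'   [gene_models()].
#' @param upstream_window promoter window size in bp (> 0).
#' @return data.frame: `locus_id`, `category` (`PRO`, `PRO2`, `GB`,
#'   `none`), `symbols`, `transcripts` (space-separated).
#' @export
map_to_genes <- function(loci, genes, upstream_window = 10000) {
  if (inherits(loci, "MethylationMatrix")) loci <- loci$loci
  if (upstream_window <= 0) stop("upstream_window must be > 0")
  gr <- as_granges(loci)

  body_gr <- as_granges(genes)
  prom <- data.frame(
    chrom = genes$chrom,
    start = ifelse(genes$strand == "+",
                   pmax(0, genes$tss - upstream_window), genes$tss + 1),
    end = ifelse(genes$strand == "+",
                 genes$tss, genes$tss + 1 + upstream_window),
    strand = genes$strand
  )
  keep <- prom$start < prom$end   # genes at chromosome start may have no window
  prom_gr <- as_granges(prom[keep, , drop = FALSE])
  prom_idx <- which(keep)

  gb_hits <- GenomicRanges::findOverlaps(gr, body_gr, minoverlap = 1L,
                                         ignore.strand = TRUE)
  pro_hits <- GenomicRanges::findOverlaps(gr, prom_gr, minoverlap = 1L,
                                          ignore.strand = TRUE)

  n <- nrow(loci)
  category <- rep("none", n)
  symbols <- character(n)
  transcripts <- character(n)
  gb_by <- split(S4Vectors::subjectHits(gb_hits), S4Vectors::queryHits(gb_hits))
  pro_by <- split(prom_idx[S4Vectors::subjectHits(pro_hits)],
                  S4Vectors::queryHits(pro_hits))
  for (i in seq_len(n)) {
    gb_genes <- gb_by[[as.character(i)]]
    pro_genes <- setdiff(pro_by[[as.character(i)]], gb_genes)  # GB beats PRO per gene
    all_genes <- union(gb_genes, pro_genes)
    if (!length(all_genes)) next
    if (length(gb_genes)) {
      category[i] <- "GB"
    } else if (length(unique(genes$strand[pro_genes])) >= 2) {
      category[i] <- "PRO2"
    } else {
      category[i] <- "PRO"
    }
    all_genes <- sort(all_genes)
    symbols[i] <- paste(genes$symbol[all_genes], collapse = " ")
    transcripts[i] <- paste(genes$transcript[all_genes], collapse = " ")
  }
  data.frame(locus_id = loci$locus_id, category = category,
             symbols = symbols, transcripts = transcripts,
             stringsAsFactors = FALSE)
}

#' Hypergeometric enrichment score
#'
#' The right-tailed Fisher/hypergeometric score used to rank gene networks:
#' with `list_size` genes of interest drawn from a `universe` containing
#' `set_size` members of a functional set, the score is `-log10` of
#' `P(X >= overlap)` for `X ~ Hypergeometric`. The tail probability is an
#' exact summation (no normal approximation).
#'
#' @param overlap observed overlap count.
#' @param list_size size of the query list.
#' @param set_size size of the functional set within the universe.
#' @param universe universe size.
#' @return list with `p` (right-tail probability) and `score` (`-log10 p`).
#' @examples
#' enrichment_score(3, 5, 6, 20)
#' @export
enrichment_score <- function(overlap, list_size, set_size, universe) {
  if (overlap > min(list_size, set_size) || overlap < 0 ||
      set_size > universe || list_size > universe)
    stop("inconsistent counts: need overlap <= min(list_size, set_size) and ",
         "set_size, list_size <= universe")
  p <- stats::phyper(overlap - 1, m = set_size, n = universe - set_size,
                     k = list_size, lower.tail = FALSE)
  p <- min(1, max(0, p))
  list(p = p, score = -log10(p))
}

#' Build a candidate-table report
#'
#' One row per candidate locus in the style of a published candidate table:
#' 1-based printed position, group means, case-minus-control difference,
#' p-value scaled by 1e6 for display, feature-overlap columns, gene
#' category and symbols; sorted ascending by p.
#'
#' @param candidates `LocusStats` rows for the candidate loci.
#' @param flags overlap flag table from [overlap_flags()] (optional).
#' @param assignments gene assignment table from [map_to_genes()] (optional).
#' @return data.frame report.
#' @export
build_candidate_report <- function(candidates, flags = NULL, assignments = NULL) {
  report <- data.frame(
    position = format_locus_keys(candidates$chrom, candidates$start,
                                 candidates$end),
    locus_id = candidates$locus_id,
    mean_case = round(candidates$mean_case, 2),
    mean_control = round(candidates$mean_control, 2),
    difference = round(candidates$mean_case - candidates$mean_control, 2),
    p_x1e6 = round(candidates$p * 1e6, 1),
    stringsAsFactors = FALSE
  )
  merge_on <- function(report, tbl, what) {
    idx <- match(report$locus_id, tbl$locus_id)
    if (anyNA(idx)) stop("unmatched locus ID in ", what, ": ",
                         report$locus_id[is.na(idx)][1])
    cbind(report, tbl[idx, setdiff(names(tbl), "locus_id"), drop = FALSE])
  }
  if (!is.null(flags)) report <- merge_on(report, flags, "overlap flags")
  if (!is.null(assignments)) report <- merge_on(report, assignments,
                                                "gene assignments")
  report <- report[order(report$p_x1e6, -abs(report$difference)), , drop = FALSE]
  rownames(report) <- NULL
  report
}
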