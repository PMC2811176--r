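# One-call orchestration: simulate -> normalize -> qc -> scan -> annotate ->
# power -> concord, driven by a YAML config with a single global seed from
# which per-stage seeds are derived deterministically.

# Deterministic per-stage seed below 2^31, derived from the global seed and
# the stage name so one number reproduces the whole run.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Run the full analysis pipeline from a config
#'
#' Executes the requested stages in order (`simulate`, `normalize`, `qc`,
#' `scan`, `annotate`, `power`, `concord`), writing every intermediate
#' artifact plus a JSON provenance record into `out_dir`. Reruns with the
#' same config and seed are identical.
#'
#' The config (YAML file or list) has a mandatory global `seed`, a `stages`
#' vector, and one optional section per stage. Stages that need the ratio
#' matrix either consume the `simulate` stage's output or explicit `matrix`
#' / `samples` paths in the config.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$seed)) stop("config must set a global 'seed'")
  stages <- cfg$stages
  if (is.null(stages)) stop("config must list 'stages'")
  known <- c("simulate", "normalize", "qc", "scan", "annotate", "power",
             "concord")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(msg)
    cat(msg, "\n", file = logf, append = TRUE)
  }

  res <- list()
  cohort <- NULL
  mat <- NULL
  samples <- NULL
  need_matrix <- function(stage) {
    if (!is.null(mat)) return(invisible())
    if (!is.null(cfg$matrix) && !is.null(cfg$samples)) {
      mat <<- read_ratio_matrix(cfg$matrix)
      samples <<- read_sample_table(cfg$samples)
    } else {
      stop("stage '", stage, "' needs a ratio matrix: run the 'simulate' ",
           "stage first or set 'matrix' and 'samples' paths in the config")
    }
  }

  if ("simulate" %in% stages) {
    log_line("stage simulate")
    sc <- do.call(simulation_config,
                  c(cfg$simulate, list(seed = stage_seed(cfg$seed, "simulate"))))
    cohort <- simulate_cohort(sc)
    mat <- cohort$matrix
    samples <- cohort$samples
    write_ratio_matrix(mat, file.path(out_dir, "matrix.tsv"))
    write_sample_table(samples, file.path(out_dir, "samples.tsv"))
    data.table::fwrite(cohort$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE)
    ann <- simulate_annotation_tracks(cohort)
    dir.create(file.path(out_dir, "tracks"), showWarnings = FALSE)
    for (tr in ann$tracks)
      write_intervals(tr, file.path(out_dir, "tracks",
                                    paste0(tr$name, ".bed")))
    write_gene_models(ann$genes, file.path(out_dir, "genes.tsv"))
    res$simulate <- list(cohort = cohort, annotation = ann)
  }

  if ("normalize" %in% stages) {
    log_line("stage normalize")
    need_matrix("normalize")
    mat <- quantile_normalize(mat)
    if (isTRUE(cfg$normalize$center)) mat <- center_arrays(mat)
    write_ratio_matrix(mat, file.path(out_dir, "norm.tsv"))
    res$normalize <- mat
  }

  if ("qc" %in% stages) {
    log_line("stage qc")
    need_matrix("qc")
    qc <- qc_report(mat)
    dir.create(file.path(out_dir, "qc"), showWarnings = FALSE)
    data.table::fwrite(as.data.frame(qc$correlations),
                       file.path(out_dir, "qc", "correlations.tsv"),
                       sep = "\t", row.names = TRUE, quote = FALSE)
    write_tree_newick(ward_cluster(mat), file.path(out_dir, "qc", "tree.nwk"))
    res$qc <- qc
  }

  scan_res <- NULL
  if ("scan" %in% stages) {
    log_line("stage scan")
    need_matrix("scan")
    n_perm <- cfg$scan$n_perm %||% 100
    scheme <- cfg$scan$scheme %||% "within_pair_flip"
    stats <- paired_t_scan(mat, samples)
    stats$rank_score <- unname(rank_scores(mat, samples))
    null <- permutation_null(mat, samples, n_perm = n_perm, scheme = scheme,
                             seed = stage_seed(cfg$seed, "scan"))
    thr <- significance_threshold(null)
    cand <- select_candidates(stats, thr$alpha_star,
                              cfg$scan$moderate_alpha %||%
                                (10 * thr$alpha_star))
    dir.create(file.path(out_dir, "scan"), showWarnings = FALSE)
    wr <- function(df, f) data.table::fwrite(df, file.path(out_dir, "scan", f),
                                             sep = "\t", quote = FALSE,
                                             na = "NA")
    wr(stats, "locus_stats.tsv")
    wr(data.frame(permutation = seq_along(null$min_p), min_p = null$min_p,
                  scheme = null$scheme), "null_summary.tsv")
    wr(cand$histogram, "histogram.tsv")
    wr(cand$significant, "candidates_significant.tsv")
    wr(cand$moderate, "candidates_moderate.tsv")
    scan_res <- list(stats = stats, null = null, threshold = thr,
                     candidates = cand)
    res$scan <- scan_res
  }

  if ("annotate" %in% stages) {
    log_line("stage annotate")
    if (is.null(scan_res))
      stop("stage 'annotate' needs the 'scan' stage output")
    ann <- res$simulate$annotation
    if (is.null(ann) && is.null(cfg$annotate$tracks))
      stop("stage 'annotate' needs annotation tracks: simulate them or set ",
           "'annotate: tracks:' paths in the config")
    if (is.null(ann)) {
      kinds <- cfg$annotate$kinds %||%
        rep("other", length(cfg$annotate$tracks))
      tracks <- Map(read_intervals, cfg$annotate$tracks, kinds)
      genes <- read_gene_models(cfg$annotate$genes)
    } else {
      tracks <- ann$tracks
      genes <- ann$genes
    }
    cand <- scan_res$candidates$significant
    if (nrow(cand)) {
      flags <- overlap_flags(cand, tracks)
      assign <- map_to_genes(cand, genes)
      report <- build_candidate_report(cand, flags, assign)
    } else {
      report <- build_candidate_report(cand)
    }
    data.table::fwrite(report, file.path(out_dir, "candidate_report.tsv"),
                       sep = "\t", quote = FALSE, na = "NA")
    res$annotate <- report
  }

  if ("power" %in% stages) {
    log_line("stage power")
    pg <- power_grid(ns = unlist(cfg$power$ns) %||% c(5, 10, 15, 25, 35, 50, 100),
                     alphas = unlist(cfg$power$alphas) %||% c(0.05, 1e-5, 1e-10),
                     delta = cfg$power$delta %||% 0.60,
                     sigma = cfg$power$sigma %||% 0.32,
                     reps = cfg$power$reps %||% 2e5,
                     seed = stage_seed(cfg$seed, "power"))
    data.table::fwrite(as.data.frame(pg), file.path(out_dir, "power.tsv"),
                       sep = "\t", quote = FALSE)
    res$power <- pg
  }

  if ("concord" %in% stages) {
    log_line("stage concord")
    need_matrix("concord")
    bis <- simulate_bisulphite(mat,
                               noise_sd_percent =
                                 cfg$concord$noise_sd_percent %||% 5,
                               seed = stage_seed(cfg$seed, "concord"))
    per_locus <- stats::aggregate(percent ~ locus_id, bis, mean)
    ratio <- rowMeans(mat$values, na.rm = TRUE)
    idx <- match(per_locus$locus_id, names(ratio))
    conc <- platform_concordance(ratio[idx], per_locus$percent,
                                 per_locus$locus_id)
    data.table::fwrite(conc$residuals, file.path(out_dir, "concordance.tsv"),
                       sep = "\t", quote = FALSE)
    res$concord <- conc
  }

  prov <- list(
    config = cfg,
    stage_seeds = stats::setNames(
      lapply(stages, function(s) stage_seed(cfg$seed, s)), stages),
    package_version = as.character(utils::packageVersion("helpscan")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_line("done: ", length(stages), " stage(s)")
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
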