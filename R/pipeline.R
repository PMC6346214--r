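#' Pipeline run configuration
#'
#' Collects every numeric convention of the analysis in one serialisable
#' object: filter thresholds (5 TPM global and per-time-point means, 150 bp
#' minimum length, fewer than 5 zero-TPM individuals), the HVG test
#' settings (minimum biological CV 0.10, FDR 0.10), the LVG set size
#' (1,000), the number of size-matched random sets (1,000), the cluster
#' count (4) and the size-matched length window (1,100-1,400 bp).
#'
#' @param min_global_mean,min_tp_mean,min_length,max_zeros filter thresholds.
#' @param min_biol_cv,fdr HVG test settings.
#' @param n_lvg,n_random_sets,k_clusters,size_window downstream settings.
#' @param sharing_method "conditional" or "jaccard".
#' @param linkage hclust linkage (default "complete").
#' @param cor_method correlation flavour (default "spearman").
#' @param seed integer seed for the random reference sets.
#' @return list of class `run_config`; round-trips through YAML unchanged.
#' @export
run_config <- function(min_global_mean = 5, min_tp_mean = 5,
                       min_length = 150, max_zeros = 5,
                       min_biol_cv = 0.10, fdr = 0.10,
                       n_lvg = 1000, n_random_sets = 1000,
                       k_clusters = 4, size_window = c(1100, 1400),
                       sharing_method = "conditional",
                       linkage = "complete", cor_method = "spearman",
                       seed = 1L) {
  stopifnot(min_global_mean > 0, min_tp_mean > 0, min_length > 0,
            max_zeros > 0, min_biol_cv >= 0, fdr > 0, fdr < 1,
            n_lvg > 0, n_random_sets > 0, k_clusters >= 2)
  structure(list(
    min_global_mean = min_global_mean, min_tp_mean = min_tp_mean,
    min_length = min_length, max_zeros = max_zeros,
    min_biol_cv = min_biol_cv, fdr = fdr,
    n_lvg = as.integer(n_lvg), n_random_sets = as.integer(n_random_sets),
    k_clusters = as.integer(k_clusters), size_window = size_window,
    sharing_method = sharing_method, linkage = linkage,
    cor_method = cor_method, seed = as.integer(seed)
  ), class = "run_config")
}

#' Save / load a run configuration as YAML
#' @param config a [run_config()].
#' @param path YAML file path.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full variability analysis
#'
#' Orchestrates the per-time-point pipeline end to end: TPM conversion (when
#' counts are supplied), the four gene filters, trend fit and variability
#' table per time-point, HVG / LVG / random reference sets, and the
#' time-course assembly (sharing matrix, day/night summary, profile
#' clustering, expression-variability correlation). Deterministic given
#' config and inputs; when `out_dir` is given, every stage output is written
#' as TSV.
#'
#' @param matrices named list of genes x individuals matrices, one per
#'   time-point, in time order.
#' @param gene_lengths named numeric vector of gene lengths (bp).
#' @param unit "counts" (TPM computed internally) or "tpm".
#' @param config a [run_config()].
#' @param phase optional per-time-point phase tags (see
#'   [build_timecourse()]).
#' @param out_dir optional output directory for stage TSVs.
#' @return list of class `run_result`: `tables` (per-time-point variability
#'   tables), `hvg_sets`, `lvg_sets`, `random_sets`, `timecourse`,
#'   `sharing`, `day_night`, `clusters`, `profile_cor`, and `report`
#'   (per-stage gene counts, trend parameters, warnings).
#' @export
run_pipeline <- function(matrices, gene_lengths, unit = c("tpm", "counts"),
                         config = run_config(), phase = NULL, out_dir = NULL) {
  unit <- match.arg(unit)
  tps <- names(matrices)
  if (is.null(tps)) stop("matrices must be a named list (time-point labels)")

  tpm <- if (unit == "counts") {
    lapply(matrices, compute_tpm, gene_lengths = gene_lengths)
  } else {
    matrices
  }

  report <- list(timepoints = tps, filter = list(), trend = list(),
                 warnings = character(0))
  tables <- hvg_sets <- lvg_sets <- rnd_sets <- vector("list", length(tps))
  names(tables) <- names(hvg_sets) <- names(lvg_sets) <- names(rnd_sets) <- tps

  for (t in tps) {
    fl <- filter_genes(tpm, t, gene_lengths,
                       min_global_mean = config$min_global_mean,
                       min_length = config$min_length,
                       max_zeros = config$max_zeros,
                       min_tp_mean = config$min_tp_mean)
    report$filter[[t]] <- attr(fl$report, "counts")
    sub <- tpm[[t]][fl$genes, , drop = FALSE]
    tab <- withCallingHandlers(
      variability_table(sub, timepoint = t, fdr = config$fdr,
                        min_biol_cv = config$min_biol_cv),
      warning = function(w) {
        report$warnings <<- c(report$warnings,
                              paste0(t, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    fit <- attr(tab, "fit")
    report$trend[[t]] <- c(a0 = fit$a0, a1 = fit$a1,
                           n_fit = length(fit$fit_gene_ids))
    tables[[t]] <- tab
    hvg_sets[[t]] <- select_hvg(tab, config$fdr)
    lvg_sets[[t]] <- select_lvg(tab, config$n_lvg)
    rnd_sets[[t]] <- sample_random_sets(tab$gene_id, length(hvg_sets[[t]]),
                                        n_sets = config$n_random_sets,
                                        seed = config$seed + match(t, tps))
  }

  tc <- build_timecourse(tables, lvg_n = config$n_lvg, phase = phase)
  sharing <- pairwise_sharing(tc$hvg, method = config$sharing_method)
  day_night <- tryCatch(day_night_summary(sharing, tc$phase),
                        error = function(e) {
                          report$warnings <<- c(report$warnings,
                                                conditionMessage(e))
                          NULL
                        })

  union_hvg <- rownames(tc$hvg)[rowSums(tc$hvg) > 0]
  clusters <- NULL
  profile_cor <- NULL
  if (length(union_hvg) >= config$k_clusters) {
    cc2 <- tc$corrected_cv2[union_hvg, , drop = FALSE]
    clusters <- tryCatch(
      cluster_profiles(cc2, k = config$k_clusters, linkage = config$linkage),
      error = function(e) NULL)
    expr <- sapply(tps, function(t) {
      mt <- stats::setNames(tables[[t]]$mean_tpm, tables[[t]]$gene_id)
      mt[union_hvg]
    })
    rownames(expr) <- union_hvg
    expr_norm <- suppressWarnings(mean_normalize(expr))
    profile_cor <- profile_correlation(expr_norm, cc2,
                                       method = config$cor_method)
  }

  res <- structure(list(
    tables = tables, hvg_sets = hvg_sets, lvg_sets = lvg_sets,
    random_sets = rnd_sets, timecourse = tc, sharing = sharing,
    day_night = day_night, clusters = clusters, profile_cor = profile_cor,
    report = report, config = config
  ), class = "run_result")

  if (!is.null(out_dir)) write_run_result(res, out_dir)
  res
}

#' Write all stage outputs of a pipeline run
#'
#' One TSV per stage under `dir`: per-time-point variability tables, HVG and
#' LVG lists, the corrected-CV2 and membership matrices, the sharing matrix,
#' cluster assignments, per-gene profile correlations, and a YAML run
#' report.
#'
#' @param res a `run_result` from [run_pipeline()].
#' @param dir output directory.
#' @export
write_run_result <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  for (t in names(res$tables)) {
    wt(res$tables[[t]], paste0("variability_", t, ".tsv"))
    writeLines(res$hvg_sets[[t]], file.path(dir, paste0("hvg_", t, ".tsv")))
    writeLines(res$lvg_sets[[t]], file.path(dir, paste0("lvg_", t, ".tsv")))
  }
  cc2 <- res$timecourse$corrected_cv2
  wt(data.frame(gene_id = rownames(cc2), cc2, check.names = FALSE),
     "corrected_cv2_matrix.tsv")
  memb <- res$timecourse$hvg
  wt(data.frame(gene_id = rownames(memb), memb * 1, check.names = FALSE),
     "hvg_membership.tsv")
  wt(data.frame(timepoint = rownames(res$sharing), res$sharing,
                check.names = FALSE), "sharing_matrix.tsv")
  if (!is.null(res$clusters)) {
    lab <- res$clusters$labels
    wt(data.frame(gene_id = names(lab), cluster = unname(lab)),
       "clusters.tsv")
  }
  if (!is.null(res$profile_cor)) wt(res$profile_cor, "profile_correlation.tsv")
  rep_out <- res$report
  rep_out$trend <- lapply(rep_out$trend, as.list)
  rep_out$filter <- lapply(rep_out$filter, as.list)
  yaml::write_yaml(rep_out, file.path(dir, "run_report.yaml"))
  invisible(dir)
}
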