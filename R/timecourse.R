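#' Assemble per-time-point variability tables into a time course
#'
#' Builds gene x time-point matrices of corrected CV2 and of HVG / LVG
#' membership from a list of [variability_table()] results. Genes are the
#' union over time-points; missing gene/time-point combinations (gene
#' filtered out at that time-point) are NA in the corrected-CV2 matrix and
#' FALSE in the membership matrices.
#'
#' @param tables named list of variability tables (names = time-point labels,
#'   in time order).
#' @param lvg_n LVG set size per time-point (default 1000).
#' @param phase optional character vector of phase tags per time-point
#'   ("day" / "dusk" / "night" / "dawn"); default tags the first half "day"
#'   and the second half "night", with the last day time-point as "dusk" and
#'   the last night one as "dawn", mirroring a ZT2-ZT24 design.
#' @return list of class `timecourse`: `corrected_cv2`, `hvg`, `lvg`
#'   matrices; `timepoints`; `phase`.
#' @export
build_timecourse <- function(tables, lvg_n = 1000, phase = NULL) {
  tps <- names(tables)
  if (is.null(tps)) stop("tables must be a named list")
  genes <- sort(unique(unlist(lapply(tables, `[[`, "gene_id"))))
  cc2 <- matrix(NA_real_, length(genes), length(tps),
                dimnames = list(genes, tps))
  hvg <- lvg <- matrix(FALSE, length(genes), length(tps),
                       dimnames = list(genes, tps))
  for (t in tps) {
    tab <- tables[[t]]
    cc2[tab$gene_id, t] <- tab$corrected_cv2
    hvg[select_hvg(tab), t] <- TRUE
    lvg[select_lvg(tab, lvg_n), t] <- TRUE
  }
  if (is.null(phase)) {
    half <- ceiling(length(tps) / 2)
    phase <- rep(c("day", "night"), c(half, length(tps) - half))
    phase[half] <- "dusk"
    phase[length(tps)] <- "dawn"
  }
  structure(list(corrected_cv2 = cc2, hvg = hvg, lvg = lvg,
                 timepoints = tps, phase = phase),
            class = "timecourse")
}

#' Distribution of per-gene membership counts over time-points
#'
#' For genes that are in the set (HVG or LVG) at least once, tabulates at how
#' many time-points each is a member. The histogram totals the union-set
#' size.
#'
#' @param membership logical genes x time-points matrix.
#' @return integer vector indexed 1..n_timepoints.
#' @export
timepoint_count_distribution <- function(membership) {
  n <- rowSums(membership)
  tabulate(n[n > 0], nbins = ncol(membership))
}

#' Pairwise sharing of variable-gene sets between time-points
#'
#' Cell (i, j) is the percentage of time-point i's set also found at
#' time-point j: 100 * |S_i intersect S_j| / |S_i| (row-conditioned), or the
#' Jaccard percentage 100 * |intersect| / |union| when `method = "jaccard"`.
#' The diagonal is 100. A time-point with an empty set gives an NA row
#' (and NA column under Jaccard).
#'
#' @param membership logical genes x time-points matrix.
#' @param method "conditional" (default) or "jaccard".
#' @return numeric time-point x time-point matrix of percentages.
#' @export
pairwise_sharing <- function(membership, method = c("conditional", "jaccard")) {
  method <- match.arg(method)
  if (ncol(membership) < 2) stop("need at least 2 time-points")
  m <- membership * 1
  inter <- crossprod(m)           # |S_i intersect S_j|
  sizes <- diag(inter)
  denom <- if (method == "conditional") {
    matrix(sizes, ncol(m), ncol(m))
  } else {
    outer(sizes, sizes, "+") - inter
  }
  out <- 100 * inter / denom
  out[!is.finite(out)] <- NA_real_
  diag(out)[sizes > 0] <- 100
  dimnames(out) <- list(colnames(membership), colnames(membership))
  out
}

#' Day / night sharing summary
#'
#' Averages the off-diagonal sharing percentages within day time-points,
#' within night time-points, and between the two phases. Time-points tagged
#' with phases in `exclude` (dusk/dawn by default only "dusk", following the
#' convention of dropping the time-point just before lights-off) are left out
#' of all three averages.
#'
#' @param sharing matrix from [pairwise_sharing()].
#' @param phase character vector of phase tags per time-point.
#' @param exclude phase tags to drop (default "dusk").
#' @return named numeric vector: within_day, within_night, between.
#' @export
day_night_summary <- function(sharing, phase, exclude = "dusk") {
  keep <- !(phase %in% exclude)
  ph <- phase[keep]
  ph[ph == "dawn"] <- "night"
  s <- sharing[keep, keep, drop = FALSE]
  day <- which(ph == "day"); night <- which(ph == "night")
  if (length(day) < 2 || length(night) < 2) {
    stop("need at least 2 time-points per phase")
  }
  offmean <- function(block) mean(block[row(block) != col(block)], na.rm = TRUE)
  c(
    within_day = offmean(s[day, day, drop = FALSE]),
    within_night = offmean(s[night, night, drop = FALSE]),
    between = mean(c(s[day, night], s[night, day]), na.rm = TRUE)
  )
}

#' Cluster variability profiles
#'
#' Agglomerative clustering of gene profiles with distance
#' 1 - Pearson correlation and (by default) complete linkage, cut into k
#' clusters. Genes with constant (zero-variance) or incomplete profiles get
#' an NA label and are recorded in the `"dropped"` attribute.
#'
#' @param mat numeric genes x time-points matrix (e.g. corrected CV2 of the
#'   union HVG set).
#' @param k number of clusters (default 4).
#' @param linkage linkage method for [stats::hclust()] (default "complete").
#' @return list with `labels` (named integer vector, NA for dropped genes)
#'   and `tree` (the hclust object).
#' @export
cluster_profiles <- function(mat, k = 4, linkage = "complete") {
  if (k < 2) stop("k must be at least 2")
  ok <- apply(mat, 1, function(x) all(is.finite(x)) && stats::sd(x) > 0)
  if (sum(ok) < k) stop("fewer usable profiles than clusters")
  d <- stats::as.dist(1 - stats::cor(t(mat[ok, , drop = FALSE])))
  tree <- stats::hclust(d, method = linkage)
  cut <- stats::cutree(tree, k = k)
  labels <- stats::setNames(rep(NA_integer_, nrow(mat)), rownames(mat))
  labels[names(cut)] <- cut
  out <- list(labels = labels, tree = tree)
  if (any(!ok)) attr(out, "dropped") <- rownames(mat)[!ok]
  out
}

#' Correlation between expression and variability profiles
#'
#' Per gene, correlates the mean-normalised expression profile with the
#' corrected-CV2 profile across time-points and classifies genes into
#' significant-positive / significant-negative / non-significant at
#' `alpha` (two-sided). Spearman by default.
#'
#' @param expr_profiles genes x time-points matrix of mean-normalised
#'   expression.
#' @param var_profiles matching matrix of corrected CV2.
#' @param method "spearman" (default) or "pearson".
#' @param alpha significance split (default 0.05).
#' @return data.frame: gene_id, r, p, class.
#' @export
profile_correlation <- function(expr_profiles, var_profiles,
                                method = c("spearman", "pearson"),
                                alpha = 0.05) {
  method <- match.arg(method)
  genes <- rownames(expr_profiles)
  stopifnot(identical(dim(expr_profiles), dim(var_profiles)))
  res <- lapply(seq_along(genes), function(i) {
    x <- expr_profiles[i, ]; y <- var_profiles[i, ]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(c(NA_real_, NA_real_))
    }
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = method,
                                           exact = FALSE))
    c(ct$estimate, ct$p.value)
  })
  res <- do.call(rbind, res)
  cls <- rep("non_significant", length(genes))
  cls[!is.na(res[, 2]) & res[, 2] <= alpha & res[, 1] > 0] <- "significant_positive"
  cls[!is.na(res[, 2]) & res[, 2] <= alpha & res[, 1] < 0] <- "significant_negative"
  cls[is.na(res[, 2])] <- NA_character_
  data.frame(gene_id = genes, r = res[, 1], p = res[, 2], class = cls,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Stability of corrected CV2 under individual subsampling
#'
#' For each subset size, repeatedly draws random subsets of individuals,
#' reruns the per-time-point pipeline (filter, trend fit, corrected CV2) on
#' the subset, and reports the mean rank correlation with the corrected CV2
#' computed from all individuals, over genes retained in both runs. Used to
#' decide how many individuals saturate the variability estimate.
#'
#' @param tpm full TPM matrix for one time-point (genes x M individuals).
#' @param gene_lengths named vector of gene lengths (bp).
#' @param sizes subset sizes to evaluate (each in [2, M]).
#' @param n_draws subset draws per size (default 20).
#' @param seed integer seed.
#' @param method correlation flavour (default "spearman").
#' @param ... thresholds passed to [filter_genes()].
#' @return data.frame: size, mean_cor, sd_cor, n_draws.
#' @export
subsample_stability <- function(tpm, gene_lengths, sizes, n_draws = 20,
                                seed = 1L, method = "spearman", ...) {
  M <- ncol(tpm)
  if (any(sizes < 2 | sizes > M)) stop("subset sizes must lie in [2, M]")
  cc2_of <- function(mat) {
    fl <- filter_genes(list(tp = mat), "tp", gene_lengths, ...)
    sub <- mat[fl$genes, , drop = FALSE]
    tab <- variability_table(sub)
    stats::setNames(tab$corrected_cv2, tab$gene_id)
  }
  full <- cc2_of(tpm)
  with_seed(seed, {
    out <- lapply(sizes, function(sz) {
      cors <- vapply(seq_len(n_draws), function(d) {
        cols <- if (sz == M) seq_len(M) else sample.int(M, sz)
        sub <- suppressWarnings(cc2_of(tpm[, cols, drop = FALSE]))
        shared <- intersect(names(sub), names(full))
        shared <- shared[is.finite(sub[shared]) & is.finite(full[shared])]
        stats::cor(sub[shared], full[shared], method = method)
      }, numeric(1))
      data.frame(size = sz, mean_cor = mean(cors), sd_cor = stats::sd(cors),
                 n_draws = n_draws)
    })
    do.call(rbind, out)
  })
}
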