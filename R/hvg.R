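#' Fit the CV2-mean trend
#'
#' Fits CV2 = a1/mu + a0 by a gamma-family GLM with identity link (iteratively
#' reweighted least squares), the standard model for the mean dependence of
#' expression variability. The fit subset is restricted to genes whose mean is
#' at least `min_mean_for_fit`; when that threshold is not given it is taken
#' as the `fit_quantile` quantile of means among genes with CV2 above
#' `cv2_floor`, which anchors the fit away from the noisiest low-expression
#' genes while keeping the informative 1/mu range.
#'
#' @param means positive numeric vector of per-gene mean expression (TPM).
#' @param cv2s matching vector of per-gene squared coefficients of variation.
#' @param min_mean_for_fit optional explicit mean threshold for the fit subset.
#' @param fit_quantile quantile used to derive `min_mean_for_fit` (default 0.4).
#' @param cv2_floor CV2 floor for the quantile computation (default 0.05).
#' @param min_fit_genes minimum fit-subset size (default 50).
#' @return object of class `trend_fit`: list with `a0`, `a1`,
#'   `fit_gene_ids`, `min_mean_for_fit`, and `method` ("glmgam" or the
#'   least-squares fallback "ols").
#' @export
fit_cv2_trend <- function(means, cv2s, min_mean_for_fit = NULL,
                          fit_quantile = 0.4, cv2_floor = 0.05,
                          min_fit_genes = 50) {
  if (length(means) != length(cv2s)) stop("means and cv2s must match")
  ids <- names(means)
  if (is.null(ids)) ids <- as.character(seq_along(means))
  ok <- is.finite(means) & is.finite(cv2s) & means > 0 & cv2s > 0
  means <- means[ok]; cv2s <- cv2s[ok]; ids <- ids[ok]

  if (is.null(min_mean_for_fit)) {
    anchor <- means[cv2s > cv2_floor]
    min_mean_for_fit <- if (length(anchor)) {
      unname(stats::quantile(anchor, fit_quantile))
    } else {
      unname(stats::quantile(means, fit_quantile))
    }
  }
  use <- means >= min_mean_for_fit
  if (sum(use) < min_fit_genes) {
    stop("fewer than ", min_fit_genes, " genes in the fit subset")
  }
  x <- 1 / means[use]
  y <- cv2s[use]
  if (stats::sd(x) == 0) stop("all means equal: trend is unidentifiable")

  start <- stats::coef(stats::lm(y ~ x))
  fit <- tryCatch({
    g <- suppressWarnings(stats::glm(
      y ~ x, family = stats::Gamma(link = "identity"),
      start = pmax(start, c(1e-8, 1e-8)),
      control = stats::glm.control(epsilon = 1e-8, maxit = 100)
    ))
    if (!g$converged) stop("IRLS did not converge")
    list(coef = stats::coef(g), method = "glmgam")
  }, error = function(e) {
    warning("gamma GLM failed (", conditionMessage(e),
            "); falling back to least squares")
    list(coef = start, method = "ols")
  })

  structure(list(
    a0 = unname(fit$coef[1]),
    a1 = unname(fit$coef[2]),
    fit_gene_ids = ids[use],
    min_mean_for_fit = min_mean_for_fit,
    method = fit$method
  ), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("CV2-mean trend: CV2 = %.4g/mu + %.4g (%d genes, mean >= %.3g, %s)\n",
              x$a1, x$a0, length(x$fit_gene_ids), x$min_mean_for_fit, x$method))
  invisible(x)
}

#' Evaluate the fitted trend at given means
#'
#' @param fit a `trend_fit`.
#' @param mu positive numeric vector of means.
#' @return trend CV2 values a1/mu + a0.
#' @export
trend_cv2 <- function(fit, mu) fit$a1 / mu + fit$a0

#' Corrected CV2: log2 ratio of observed CV2 to the trend
#'
#' Positive values mean more variable than genes of the same expression
#' level; zero means on-trend. A zero CV2 yields NA (with a warning) rather
#' than -Inf.
#'
#' @param cv2 observed CV2 (vector).
#' @param mu matching means.
#' @param fit a `trend_fit`.
#' @return log2(cv2 / trend(mu)).
#' @export
corrected_cv2 <- function(cv2, mu, fit) {
  tr <- trend_cv2(fit, mu)
  bad <- !is.finite(cv2) | cv2 <= 0 | !is.finite(tr) | tr <= 0
  if (any(bad)) warning(sum(bad), " gene(s) with zero/invalid CV2 set to NA")
  out <- rep(NA_real_, length(cv2))
  out[!bad] <- log2(cv2[!bad] / tr[!bad])
  out
}

#' Chi-square test for excess variability
#'
#' Tests whether a gene's CV2 across individuals significantly exceeds the
#' trend plus a minimum biological coefficient of variation. With
#' minBiolDisp = min_biol_cv^2, the null upper bound on CV2 at mean mu is
#' cv2th = a0 + minBiolDisp + a0*minBiolDisp; the statistic
#' (m-1) * mu^2 * cv2 / [(mu*a1 + mu^2*cv2th) / (1 + cv2th/m)]
#' is referred to the upper tail of a chi-square distribution with m-1
#' degrees of freedom.
#'
#' @param mu per-gene mean (vector).
#' @param cv2 per-gene CV2 (vector).
#' @param m number of individuals.
#' @param fit a `trend_fit`.
#' @param min_biol_cv minimum biological CV the gene must exceed
#'   (default 0.10, i.e. 10%).
#' @return vector of upper-tail p-values; genes with a non-positive test
#'   denominator (pathological fit) get NA and are counted in the
#'   `"excluded"` attribute.
#' @export
test_hvg <- function(mu, cv2, m, fit, min_biol_cv = 0.10) {
  if (m < 2) stop("need at least 2 individuals")
  min_biol_disp <- min_biol_cv^2
  cv2th <- fit$a0 + min_biol_disp + fit$a0 * min_biol_disp
  denom <- (mu * fit$a1 + mu^2 * cv2th) / (1 + cv2th / m)
  stat <- (m - 1) * mu^2 * cv2 / denom
  p <- stats::pchisq(stat, df = m - 1, lower.tail = FALSE)
  bad <- !is.finite(denom) | denom <= 0 | !is.finite(cv2)
  p[bad] <- NA_real_
  if (any(bad)) attr(p, "excluded") <- sum(bad)
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (wraps [stats::p.adjust()]); NA p-values are
#' propagated.
#'
#' @param p vector of p-values in [0, 1].
#' @return adjusted p-values, monotone and capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-time-point variability table
#'
#' Runs the full per-time-point variability analysis on a filtered TPM
#' matrix: per-gene mean and CV2, trend fit (or a supplied fit), corrected
#' CV2, excess-variability p-values, BH adjustment and the HVG flag
#' (p_adj < fdr).
#'
#' @param tpm numeric TPM matrix, genes x individuals, rownames = gene IDs.
#' @param timepoint label stored in the table (e.g. "ZT2").
#' @param fit optional `trend_fit`; fitted from this matrix when NULL.
#' @param fdr FDR threshold for the HVG flag (default 0.10).
#' @param min_biol_cv minimum biological CV (default 0.10).
#' @param ... passed to [fit_cv2_trend()].
#' @return data.frame with columns gene_id, mean_tpm, cv2, trend,
#'   corrected_cv2, p, p_adj, is_hvg; attributes `fit`, `timepoint`, `m`.
#' @export
variability_table <- function(tpm, timepoint = "", fit = NULL,
                              fdr = 0.10, min_biol_cv = 0.10, ...) {
  st <- cv2_stats(tpm)
  means <- stats::setNames(st$mean, st$gene_id)
  cv2s <- stats::setNames(st$cv2, st$gene_id)
  if (is.null(fit)) fit <- fit_cv2_trend(means, cv2s, ...)
  m <- ncol(tpm)
  tab <- data.frame(
    gene_id = st$gene_id,
    mean_tpm = st$mean,
    cv2 = st$cv2,
    trend = trend_cv2(fit, st$mean),
    corrected_cv2 = suppressWarnings(corrected_cv2(cv2s, means, fit)),
    stringsAsFactors = FALSE
  )
  tab$p <- as.numeric(test_hvg(tab$mean_tpm, tab$cv2, m, fit, min_biol_cv))
  tab$p_adj <- bh_adjust(tab$p)
  tab$is_hvg <- !is.na(tab$p_adj) & tab$p_adj < fdr
  attr(tab, "fit") <- fit
  attr(tab, "timepoint") <- timepoint
  attr(tab, "m") <- m
  tab
}

#' Select highly variable genes
#'
#' Genes whose BH-adjusted p-value falls strictly below the FDR threshold.
#'
#' @param table a [variability_table()] result.
#' @param fdr FDR threshold (default 0.10).
#' @return character vector of HVG IDs (sorted).
#' @export
select_hvg <- function(table, fdr = 0.10) {
  sort(table$gene_id[!is.na(table$p_adj) & table$p_adj < fdr])
}

#' Select lowly variable genes
#'
#' The `n` genes with the smallest corrected CV2 (ties broken by gene ID for
#' determinism). If fewer than `n` genes have a finite corrected CV2, all are
#' returned, ranked.
#'
#' @param table a [variability_table()] result.
#' @param n set size (default 1000).
#' @return character vector of LVG IDs in rank order.
#' @export
select_lvg <- function(table, n = 1000) {
  ok <- table[is.finite(table$corrected_cv2), , drop = FALSE]
  ord <- order(ok$corrected_cv2, ok$gene_id)
  utils::head(ok$gene_id[ord], n)
}

#' Random reference gene sets
#'
#' Simple random samples without replacement from the gene universe,
#' size-matched to an HVG set, used as an empirical null envelope.
#'
#' @param universe character vector of gene IDs.
#' @param size set size (<= length(universe)).
#' @param n_sets number of sets (default 1000).
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return list of character vectors.
#' @export
sample_random_sets <- function(universe, size, n_sets = 1000, seed = NULL) {
  if (size > length(universe)) stop("size exceeds universe")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  lapply(seq_len(n_sets), function(i) sample(universe, size))
}
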