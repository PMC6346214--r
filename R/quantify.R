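#' Convert a count matrix to TPM
#'
#' Transcripts per million: per sample, counts are divided by gene length to
#' give a length-normalised rate, and rates are rescaled to sum to one
#' million. Zero counts map to zero TPM.
#'
#' @param counts numeric matrix, genes in rows (rownames = gene IDs), samples
#'   in columns. Fractional counts are accepted.
#' @param gene_lengths numeric vector of gene lengths in bp, one per row of
#'   `counts` (recycled by name when named).
#' @return numeric matrix of TPM values, same dimensions and dimnames as
#'   `counts`; each column sums to 1e6 (columns that are all zero stay zero).
#' @export
compute_tpm <- function(counts, gene_lengths) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts))) {
    gene_lengths <- gene_lengths[rownames(counts)]
  }
  if (length(gene_lengths) != nrow(counts)) {
    stop("gene_lengths must have one entry per gene")
  }
  if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0)) {
    stop("all gene lengths must be positive and finite")
  }
  rate <- counts / gene_lengths
  denom <- colSums(rate)
  tpm <- sweep(rate, 2, ifelse(denom > 0, denom, 1), "/") * 1e6
  dimnames(tpm) <- dimnames(counts)
  tpm
}

#' Filter genes for one time-point
#'
#' Applies the four retention rules used before variability analysis:
#' (i) mean TPM across all loaded samples (all time-points pooled) at least
#' `min_global_mean`; (ii) gene length at least `min_length` bp; (iii) fewer
#' than `max_zeros` individuals with TPM of exactly 0 at the analysed
#' time-point; (iv) mean TPM at the analysed time-point at least
#' `min_tp_mean`.
#'
#' The global mean (rule i) is computed over whatever matrices are supplied
#' in `tpm_all`, so partial runs use a partial pool; the full design pools
#' 168 samples.
#'
#' @param tpm_all named list of TPM matrices (one per time-point, shared gene
#'   rows) used for the global mean.
#' @param timepoint name (in `names(tpm_all)`) of the time-point to filter.
#' @param gene_lengths named numeric vector of gene lengths in bp.
#' @param min_global_mean,min_tp_mean inclusive TPM thresholds (default 5).
#' @param min_length inclusive length threshold in bp (default 150).
#' @param max_zeros strict upper bound on the number of zero-TPM individuals
#'   at the time-point (default 5: a gene with 5 or more zeros is removed).
#' @return list with `genes` (retained gene IDs) and `report`, a data.frame
#'   of per-gene pass/fail for each rule plus overall, and an attribute
#'   `counts` summarising genes removed per rule.
#' @export
filter_genes <- function(tpm_all, timepoint, gene_lengths,
                         min_global_mean = 5, min_length = 150,
                         max_zeros = 5, min_tp_mean = 5) {
  if (!timepoint %in% names(tpm_all)) {
    stop("time-point '", timepoint, "' not found")
  }
  tp <- tpm_all[[timepoint]]
  genes <- rownames(tp)
  if (is.null(genes)) stop("TPM matrices must have gene rownames")
  if (is.null(names(gene_lengths)) || !all(genes %in% names(gene_lengths))) {
    stop("gene_lengths must be named and cover all genes")
  }
  pooled <- do.call(cbind, lapply(tpm_all, function(m) m[genes, , drop = FALSE]))

  global_mean <- rowMeans(pooled)
  tp_mean <- rowMeans(tp)
  n_zero <- rowSums(tp == 0)
  len <- gene_lengths[genes]

  report <- data.frame(
    gene_id = genes,
    pass_global_mean = global_mean >= min_global_mean,
    pass_length = len >= min_length,
    pass_zeros = n_zero < max_zeros,
    pass_tp_mean = tp_mean >= min_tp_mean,
    row.names = NULL, stringsAsFactors = FALSE
  )
  report$pass <- report$pass_global_mean & report$pass_length &
    report$pass_zeros & report$pass_tp_mean

  counts <- c(
    total = length(genes),
    fail_global_mean = sum(!report$pass_global_mean),
    fail_length = sum(!report$pass_length),
    fail_zeros = sum(!report$pass_zeros),
    fail_tp_mean = sum(!report$pass_tp_mean),
    retained = sum(report$pass)
  )
  attr(report, "counts") <- counts
  list(genes = genes[report$pass], report = report)
}

#' Mean-normalise expression profiles across a time course
#'
#' Each gene's expression at each time-point is divided by that gene's
#' average across the whole time course, so the normalised profile has mean 1.
#' Genes with a zero time-course average get an all-NA profile (recorded in
#' the `"degenerate"` attribute) rather than an error.
#'
#' @param profile numeric vector (one gene over time-points) or matrix
#'   (genes x time-points).
#' @return object of the same shape, mean-normalised per gene.
#' @export
mean_normalize <- function(profile) {
  if (is.matrix(profile)) {
    mu <- rowMeans(profile)
    bad <- !is.finite(mu) | mu <= 0
    out <- profile / ifelse(bad, NA_real_, mu)
    if (any(bad)) {
      warning(sum(bad), " gene(s) with zero time-course average set to NA")
      attr(out, "degenerate") <- rownames(profile)[bad]
    }
    return(out)
  }
  mu <- mean(profile)
  if (!is.finite(mu) || mu <= 0) {
    warning("zero time-course average; returning NA profile")
    return(rep(NA_real_, length(profile)))
  }
  profile / mu
}

#' Mean and squared coefficient of variation for one gene at one time-point
#'
#' CV2 = s^2 / mu^2 with s^2 the unbiased (n-1) sample variance across
#' individuals. Scale-invariant: multiplying all values by a constant leaves
#' CV2 unchanged.
#'
#' @param values numeric vector of expression values across individuals
#'   (length >= 2, positive mean).
#' @return list with `mean` and `cv2`.
#' @export
compute_cv2 <- function(values) {
  if (length(values) < 2) stop("need at least 2 individuals")
  mu <- mean(values)
  if (!is.finite(mu) || mu <= 0) stop("mean must be positive")
  list(mean = mu, cv2 = stats::var(values) / mu^2)
}

#' Row-wise mean and CV2 for an expression matrix
#'
#' Vectorised form of [compute_cv2()]. Genes with non-positive mean get NA
#' CV2 instead of an error.
#'
#' @param mat numeric matrix, genes x individuals (>= 2 columns).
#' @return data.frame with columns `gene_id`, `mean`, `cv2`.
#' @export
cv2_stats <- function(mat) {
  if (ncol(mat) < 2) stop("need at least 2 individuals")
  mu <- rowMeans(mat)
  v <- apply(mat, 1, stats::var)
  cv2 <- ifelse(mu > 0, v / mu^2, NA_real_)
  data.frame(gene_id = rownames(mat), mean = mu, cv2 = cv2,
             row.names = NULL, stringsAsFactors = FALSE)
}
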