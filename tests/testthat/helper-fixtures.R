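# Shared fixture builders for the test suite.

# A tiny TPM matrix with named genes and known values.
tiny_tpm <- function(values, n_ind = NULL) {
  m <- do.call(rbind, values)
  rownames(m) <- names(values)
  colnames(m) <- paste0("ind", seq_len(ncol(m)))
  m
}

# Genes placed exactly on a CV2 = a1/mu + a0 curve (no noise).
on_curve_data <- function(a1 = 2, a0 = 0.05, n = 200) {
  mu <- exp(seq(log(5), log(2000), length.out = n))
  names(mu) <- sprintf("G%03d", seq_len(n))
  list(means = mu, cv2s = a1 / mu + a0)
}

# One simulated time-point pushed through filter + variability table.
sim_one_tp <- function(seed, n_individuals = 14, hvg_fraction = 0.10, ...) {
  cfg <- sim_config(n_timepoints = 1, n_individuals = n_individuals,
                    hvg_fraction = hvg_fraction, seed = seed, ...)
  ds <- generate_dataset(cfg)
  tpm <- compute_tpm(ds$counts[[1]], ds$gene_lengths)
  list(ds = ds, tpm = tpm)
}

# Exact two-sided rank-sum p-value by enumeration of all assignments.
wilcox_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  combos <- utils::combn(length(pooled), n)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n)])
  sums <- apply(combos, 2, function(idx) sum(r[idx]))
  # two-sided: double the smaller tail (exact distribution is symmetric)
  lo <- mean(sums <= obs); hi <- mean(sums >= obs)
  min(1, 2 * min(lo, hi))
}

# Exact upper-tail hypergeometric P(X >= k) by direct enumeration.
hyper_enum_p <- function(k, K, N, n) {
  xs <- max(0, n - (N - K)):min(K, n)
  probs <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  sum(probs[xs >= k])
}

# Exact two-sided Fisher p by enumerating tables with fixed margins.
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  xs <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- choose(c1, xs) * choose(N - c1, r1 - xs) / choose(N, r1)
  obs <- choose(c1, tab[1, 1]) * choose(N - c1, tab[1, 2]) / choose(N, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
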