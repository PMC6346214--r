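test_that("trend fit recovers exact parameters from on-curve data", {
  oc <- on_curve_data(a1 = 2, a0 = 0.05)
  fit <- fit_cv2_trend(oc$means, oc$cv2s, min_mean_for_fit = 0)
  expect_equal(fit$a0, 0.05, tolerance = 1e-6)
  expect_equal(fit$a1, 2, tolerance = 1e-6)
  expect_true(all(fit$fit_gene_ids %in% names(oc$means)))
  expect_equal(trend_cv2(fit, 10), fit$a1 / 10 + fit$a0)

  # all means equal -> 1/mu column is constant, unidentifiable
  expect_error(
    fit_cv2_trend(rep(10, 100), rgamma(100, 2, 10), min_mean_for_fit = 0),
    "unidentifiable")
  expect_error(fit_cv2_trend(oc$means[1:10], oc$cv2s[1:10]), "fewer than")
})

test_that("corrected CV2 is the log2 ratio to the trend", {
  fit <- structure(list(a0 = 0.05, a1 = 2), class = "trend_fit")
  mu <- c(10, 40)
  tr <- trend_cv2(fit, mu)
  expect_equal(corrected_cv2(tr, mu, fit), c(0, 0))
  expect_equal(corrected_cv2(2 * tr, mu, fit), c(1, 1))
  expect_equal(corrected_cv2(tr / 2, mu, fit), c(-1, -1))
  expect_warning(cc <- corrected_cv2(c(0, tr[2]), mu, fit), "zero")
  expect_true(is.na(cc[1]) && !is.na(cc[2]))
})

test_that("the excess-variability statistic matches an independent chi-square evaluation", {
  # expected p-values frozen from an independent chi-square survival
  # implementation evaluated at the same statistics
  fit <- structure(list(a0 = 0.02, a1 = 1), class = "trend_fit")
  mu <- c(10, 50, 200); cv2 <- c(0.3, 0.08, 0.05)
  p <- test_hvg(mu, cv2, m = 14, fit = fit, min_biol_cv = 0.10)
  expect_equal(p,
               c(0.004680832422702396, 0.07777506594848237, 0.1392434129050217),
               tolerance = 1e-12)

  # monotone decreasing in cv2 at fixed mu, vanishing in the limit
  ps <- test_hvg(rep(50, 4), c(0.05, 0.1, 0.5, 5), 14, fit)
  expect_true(all(diff(ps) < 0))
  expect_lt(test_hvg(50, 1e6, 14, fit), 1e-300)

  # pathological fit (denominator <= 0) excluded, not mis-scored
  bad <- structure(list(a0 = -0.5, a1 = -1), class = "trend_fit")
  pb <- test_hvg(10, 0.3, 14, bad)
  expect_true(is.na(pb[1]))
  expect_identical(attr(pb, "excluded"), 1L)
})

test_that("null simulation yields approximately uniform p-values at zero CV floor", {
  ks <- vapply(1:5, function(s) {
    st <- sim_one_tp(seed = 300 + s, hvg_fraction = 0)
    tab <- variability_table(st$tpm, min_biol_cv = 0)
    suppressWarnings(stats::ks.test(tab$p, "punif")$statistic)
  }, numeric(1))
  expect_lt(mean(ks), 0.05)
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # hand application of the step-up rule: sort ascending, p_(i)*n/i,
  # enforce monotonicity from the largest rank down
  p <- c(0.001, 0.008, 0.039, 0.041, 0.5)
  expect_equal(bh_adjust(p), c(0.005, 0.02, 0.05125, 0.05125, 0.5),
               tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("HVG selection respects the FDR threshold and is nested in it", {
  st <- sim_one_tp(seed = 11)
  tab <- variability_table(st$tpm)
  hvg10 <- select_hvg(tab, 0.10)
  hvg05 <- select_hvg(tab, 0.05)
  expect_true(all(hvg05 %in% hvg10))
  expect_true(all(tab$p_adj[tab$gene_id %in% hvg10] < 0.10))
  expect_true(all(tab$is_hvg == (tab$gene_id %in% hvg10)))
  empty <- tab[0, ]
  expect_length(select_hvg(empty), 0)
})

test_that("planted HVGs are recovered across the time course at controlled FDP", {
  reps <- lapply(1:5, function(s) {
    st <- sim_one_tp(seed = 500 + s)
    tab <- variability_table(st$tpm)
    hvg <- select_hvg(tab)
    planted <- st$ds$truth$genes$gene_id[st$ds$truth$genes$is_planted_hvg]
    c(fdp = if (length(hvg)) mean(!hvg %in% planted) else 0,
      sens = mean(planted %in% hvg))
  })
  reps <- do.call(rbind, reps)
  expect_lte(mean(reps[, "fdp"]), 0.15)
  # per-time-point power at the default 4x multiplier is partial;
  # union-level recovery over the full design is tested in test-acceptance.R
  expect_gt(mean(reps[, "sens"]), 0.25)

  # planted HVGs exceed null genes in realized CV2 (one-sided rank test)
  st <- sim_one_tp(seed = 77)
  tab <- variability_table(st$tpm)
  planted <- tab$gene_id %in%
    st$ds$truth$genes$gene_id[st$ds$truth$genes$is_planted_hvg]
  wt <- stats::wilcox.test(tab$corrected_cv2[planted],
                           tab$corrected_cv2[!planted],
                           alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("LVG selection is the exact bottom-n by corrected CV2", {
  st <- sim_one_tp(seed = 21, n_genes = 200)
  tab <- variability_table(st$tpm)
  lvg <- select_lvg(tab, 50)
  ok <- tab[is.finite(tab$corrected_cv2), ]
  brute <- ok$gene_id[order(ok$corrected_cv2, ok$gene_id)][1:50]
  expect_identical(lvg, brute)
  expect_true(ok$gene_id[which.min(ok$corrected_cv2)] %in% lvg)
  # fewer genes than n: all returned, ranked
  expect_length(select_lvg(tab[1:3, ], 1000), 3)
})

test_that("random reference sets are reproducible, exhaustive at full size, and unbiased", {
  u <- sprintf("G%03d", 1:50)
  s1 <- sample_random_sets(u, 10, n_sets = 20, seed = 9)
  s2 <- sample_random_sets(u, 10, n_sets = 20, seed = 9)
  expect_identical(s1, s2)
  full <- sample_random_sets(u, 50, n_sets = 3, seed = 1)
  expect_true(all(vapply(full, function(s) setequal(s, u), logical(1))))
  expect_error(sample_random_sets(u, 51, seed = 1), "exceeds")

  sets <- sample_random_sets(u, 10, n_sets = 1000, seed = 4)
  freq <- table(factor(unlist(sets), levels = u)) / 1000
  # per-gene inclusion ~ Binomial(1000, 0.2): 5 sigma band
  expect_true(all(abs(freq - 0.2) < 5 * sqrt(0.2 * 0.8 / 1000)))
})
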