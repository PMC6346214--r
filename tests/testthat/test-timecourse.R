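make_membership <- function(sets, genes, tps) {
  m <- matrix(FALSE, length(genes), length(tps),
              dimnames = list(genes, tps))
  for (t in names(sets)) m[sets[[t]], t] <- TRUE
  m
}

test_that("membership histogram totals the union-set size", {
  genes <- sprintf("G%02d", 1:50)
  set.seed(2)
  sets <- lapply(1:4, function(i) sample(genes, 12))
  names(sets) <- paste0("ZT", c(2, 4, 6, 8))
  memb <- make_membership(sets, genes, names(sets))
  h <- timepoint_count_distribution(memb)
  expect_length(h, 4)
  expect_equal(sum(h), length(unique(unlist(sets))))
  # direct count oracle
  counts <- table(factor(rowSums(memb)[rowSums(memb) > 0], levels = 1:4))
  expect_equal(h, as.integer(counts))

  # gene in the set everywhere lands in the last bin; empty membership
  memb[1, ] <- TRUE
  expect_gte(timepoint_count_distribution(memb)[4], 1)
  empty <- memb & FALSE
  expect_equal(sum(timepoint_count_distribution(empty)), 0)
})

test_that("pairwise sharing is the row-conditioned overlap percentage", {
  genes <- c("a", "b", "c", "d", "e")
  memb <- make_membership(list(ZT2 = c("a", "b", "c", "d"), ZT4 = c("c", "d", "e")),
                          genes, c("ZT2", "ZT4"))
  s <- pairwise_sharing(memb)
  expect_equal(s["ZT2", "ZT4"], 50)
  expect_equal(s["ZT4", "ZT2"], 100 * 2 / 3)
  expect_equal(unname(diag(s)), c(100, 100))

  ident <- make_membership(list(ZT2 = c("a", "b"), ZT4 = c("a", "b")),
                           genes, c("ZT2", "ZT4"))
  expect_true(all(pairwise_sharing(ident) == 100))
  disj <- make_membership(list(ZT2 = c("a", "b"), ZT4 = c("d", "e")),
                          genes, c("ZT2", "ZT4"))
  expect_equal(pairwise_sharing(disj)["ZT2", "ZT4"], 0)
  # Jaccard variant is symmetric
  sj <- pairwise_sharing(memb, method = "jaccard")
  expect_equal(sj["ZT2", "ZT4"], sj["ZT4", "ZT2"])
  expect_equal(sj["ZT2", "ZT4"], 100 * 2 / 5)
  # empty set -> NA row
  with_empty <- make_membership(list(ZT2 = c("a"), ZT4 = character(0)),
                                genes, c("ZT2", "ZT4"))
  expect_true(is.na(pairwise_sharing(with_empty)["ZT4", "ZT2"]))
})

test_that("day/night block averages match brute-force recomputation", {
  genes <- sprintf("G%02d", 1:30)
  set.seed(4)
  sets <- lapply(1:4, function(i) sample(genes, 10))
  names(sets) <- c("D1", "D2", "N1", "N2")
  memb <- make_membership(sets, genes, names(sets))
  s <- pairwise_sharing(memb)
  dn <- day_night_summary(s, c("day", "day", "night", "night"),
                          exclude = character(0))
  expect_equal(unname(dn["within_day"]), mean(c(s[1, 2], s[2, 1])))
  expect_equal(unname(dn["within_night"]), mean(c(s[3, 4], s[4, 3])))
  expect_equal(unname(dn["between"]), mean(s[cbind(c(1,1,2,2,3,3,4,4),
                                                   c(3,4,3,4,1,2,1,2))]))

  # identical sets everywhere -> all three averages 100
  ident <- make_membership(stats::setNames(rep(list(genes[1:5]), 4),
                                           names(sets)),
                           genes, names(sets))
  dn1 <- day_night_summary(pairwise_sharing(ident),
                           c("day", "day", "night", "night"),
                           exclude = character(0))
  expect_equal(unname(dn1), c(100, 100, 100))
  expect_error(day_night_summary(s, c("day", "day", "day", "night"),
                                 exclude = character(0)), "per phase")
})

test_that("profile clustering groups identical shapes and honours the metric", {
  set.seed(6)
  base <- sin(seq(0, 2 * pi, length.out = 12))
  mat <- rbind(
    A1 = base, A2 = 3 * base + 2,      # perfectly correlated: distance 0
    B1 = -base, B2 = -2 * base + 1,    # anti-correlated with A: distance 2
    C1 = cos(seq(0, 2 * pi, length.out = 12)),
    C2 = cos(seq(0, 2 * pi, length.out = 12)) * 1.5 + rnorm(12, 0, 1e-3)
  )
  cl <- cluster_profiles(mat, k = 3)
  expect_equal(cl$labels[["A1"]], cl$labels[["A2"]])
  expect_equal(cl$labels[["B1"]], cl$labels[["B2"]])
  expect_equal(cl$labels[["C1"]], cl$labels[["C2"]])
  expect_false(cl$labels[["A1"]] == cl$labels[["B1"]])
  d <- 1 - stats::cor(t(mat))
  expect_equal(unname(d["A1", "A2"]), 0, tolerance = 1e-12)
  expect_equal(unname(d["A1", "B1"]), 2, tolerance = 1e-12)

  # permutation invariance of the partition
  perm <- sample(nrow(mat))
  cl2 <- cluster_profiles(mat[perm, ], k = 3)
  agree <- outer(cl$labels, cl$labels, "==")
  agree2 <- outer(cl2$labels[names(cl$labels)], cl2$labels[names(cl$labels)], "==")
  expect_true(all(agree == agree2))

  # constant profiles get NA labels, recorded
  mat2 <- rbind(mat, FLAT = rep(1, 12))
  cl3 <- cluster_profiles(mat2, k = 3)
  expect_true(is.na(cl3$labels[["FLAT"]]))
  expect_identical(attr(cl3, "dropped"), "FLAT")
  expect_error(cluster_profiles(mat, k = 1), "at least 2")
})

test_that("expression-variability profile correlation classifies genes", {
  x <- seq_len(12) / 6
  mat_e <- rbind(P = x, N = x, Z = x)
  mat_v <- rbind(P = x, N = -x, Z = rep(1, 12))
  pc <- profile_correlation(mat_e, mat_v, method = "pearson")
  expect_equal(pc$r[pc$gene_id == "P"], 1)
  expect_equal(pc$r[pc$gene_id == "N"], -1)
  expect_identical(pc$class[pc$gene_id == "P"], "significant_positive")
  expect_identical(pc$class[pc$gene_id == "N"], "significant_negative")
  expect_true(is.na(pc$r[pc$gene_id == "Z"]))  # constant profile undefined
})

test_that("subsampling stability is exact at full size and grows with subset size", {
  st <- sim_one_tp(seed = 31, n_individuals = 16, n_genes = 500)
  ss <- subsample_stability(st$tpm, st$ds$gene_lengths,
                            sizes = c(6, 12, 16), n_draws = 5, seed = 2)
  expect_equal(ss$mean_cor[ss$size == 16], 1)
  expect_true(all(diff(ss$mean_cor) > 0))
  expect_error(subsample_stability(st$tpm, st$ds$gene_lengths, sizes = 1),
               "sizes")
})

test_that("the assembled time course links membership, histogram and union set", {
  st <- lapply(c(ZT2 = 41, ZT4 = 42, ZT6 = 43, ZT8 = 44), function(s) {
    x <- sim_one_tp(seed = s, n_genes = 400)
    variability_table(x$tpm, paste0("s", s))
  })
  tc <- build_timecourse(st, lvg_n = 50)
  expect_equal(dim(tc$hvg), dim(tc$corrected_cv2))
  expect_type(tc$hvg[1], "logical")
  union_n <- sum(rowSums(tc$hvg) > 0)
  expect_equal(sum(timepoint_count_distribution(tc$hvg)), union_n)
  expect_equal(colSums(tc$lvg), rep(50L, 4), ignore_attr = TRUE)
  s <- pairwise_sharing(tc$hvg)
  expect_true(all(s[is.finite(s)] >= 0 & s[is.finite(s)] <= 100))
})
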