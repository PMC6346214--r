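test_that("feature comparison matches the exact rank-sum enumeration", {
  feat <- c(a = 1, b = 2, c = 3, d = 4)
  r <- compare_feature(c("a", "b"), c("c", "d"), feat)
  expect_equal(r$p, wilcox_enum_p(c(1, 2), c(3, 4)))  # = 1/3
  expect_equal(r$p, 1 / 3)

  # identical samples: p = 1
  feat2 <- c(a = 1, b = 2, c = 1, d = 2)
  r2 <- compare_feature(c("a", "b"), c("c", "d"), feat2)
  expect_equal(r2$p, 1)

  # random-set envelope brackets the null median
  set.seed(9)
  u <- sprintf("G%03d", 1:200)
  feat3 <- stats::setNames(rnorm(200, 100, 10), u)
  rs <- sample_random_sets(u, 30, n_sets = 200, seed = 3)
  r3 <- compare_feature(u[1:30], u[31:200], feat3, random_sets = rs)
  expect_true(r3$random_envelope[1] < 100 && r3$random_envelope[2] > 100)
  expect_error(compare_feature(character(0), u, feat3), "non-empty")
})

test_that("per-gene TF counts match a brute-force membership scan", {
  u <- paste0("g", 1:10)
  tfs <- list(T1 = c("g1", "g2", "g3"), T2 = c("g2", "g9"),
              T3 = c("g2", "g3"), T4 = character(0), T5 = c("g3"))
  counts <- count_tf_per_gene(tfs, u)
  brute <- vapply(u, function(g) sum(vapply(tfs, function(s) g %in% s,
                                            logical(1))), integer(1))
  expect_equal(counts, brute)
  expect_equal(unname(counts["g4"]), 0L)
  expect_equal(unname(counts["g2"]), 3L)
  expect_warning(count_tf_per_gene(list(T = c("g1", "zz")), u), "outside")
})

test_that("overrepresentation p-values equal exact hypergeometric enumeration", {
  u <- paste0("g", 1:20)
  res <- set_overrepresentation(u[1:10], list(s = u[1:10]), u)
  expect_equal(res$p, hyper_enum_p(10, 10, 20, 10))
  expect_equal(res$p, 1 / choose(20, 10))
  expect_equal(res$overlap, 10)

  # annotation = universe -> p = 1
  res2 <- set_overrepresentation(u[1:10], list(all = u), u)
  expect_equal(res2$p, 1)

  # overlap at expectation -> p >= 0.5 (enumeration-verified median property)
  res3 <- set_overrepresentation(u[1:10], list(s = u[6:15]), u)  # overlap 5 = E
  expect_equal(res3$p, hyper_enum_p(5, 10, 20, 10))
  expect_gte(res3$p, 0.5)

  batch <- set_overrepresentation(u[1:10], list(a = u[1:10], b = u[11:20]), u)
  expect_equal(batch$p_adj, bh_adjust(batch$p))
  expect_error(set_overrepresentation(character(0), list(a = u), u), "empty")
})

test_that("family enrichment matches exact table enumeration and flags excess", {
  fams <- data.frame(tf_id = paste0("T", 1:8),
                     family = rep(c("F1", "F2"), each = 4))
  hits <- c("T1", "T2", "T3", "T5")  # F1: 3/4 hit, F2: 1/4 hit
  fe <- family_enrichment(hits, fams)
  tab <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
  expect_equal(fe$p[fe$family == "F1"], fisher_enum_p(tab))
  expect_equal(fe$p[fe$family == "F1"], 34 / 70)
  expect_equal(fe$n_hits[fe$family == "F1"], 3)

  # proportional hits -> p near 1
  fe0 <- family_enrichment(c("T1", "T5"), fams)
  expect_true(all(fe0$p == 1))
  expect_error(family_enrichment(c("T1", "TX"), fams), "unlabeled")

  # planted 3x family excess detected in most replicates
  detected <- vapply(1:20, function(s) {
    set.seed(700 + s)
    f <- data.frame(tf_id = paste0("T", 1:300),
                    family = rep(paste0("F", 1:10), each = 30))
    p_hit <- ifelse(f$family == "F1", 0.6, 0.2)
    hits <- f$tf_id[stats::rbinom(300, 1, p_hit) == 1]
    fe <- family_enrichment(hits, f)
    fe$p[fe$family == "F1"] < 0.05
  }, logical(1))
  expect_gte(mean(detected), 0.90)
})

test_that("mark presence enrichment matches the hand-computed chi-square", {
  u <- paste0("g", 1:200)
  query <- u[1:50]
  mark <- c(u[1:30], u[51:80])  # 60% marked in query vs 30% overall
  pe <- presence_enrichment(query, mark, u, correct = FALSE)
  tab <- matrix(c(sum(!u %in% query & !u %in% mark),
                  sum(!u %in% query & u %in% mark),
                  sum(u %in% query & !u %in% mark),
                  sum(u %in% query & u %in% mark)), 2, byrow = TRUE)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  expect_equal(pe$p, stats::pchisq(stat, 1, lower.tail = FALSE))
  expect_equal(pe$prop_query, 0.6)
  expect_equal(pe$prop_universe, 0.3)

  # query = universe: proportions equal, p = 1
  pe1 <- presence_enrichment(u, mark, u)
  expect_equal(pe1$prop_query, pe1$prop_universe)
  expect_equal(pe1$p, 1)

  # sparse table falls back to Fisher, and the random CI brackets the null
  pe2 <- presence_enrichment(u[1:3], u[1:2], u)
  expect_identical(pe2$test, "fisher")
  rs <- sample_random_sets(u, 50, n_sets = 200, seed = 5)
  pe3 <- presence_enrichment(u[1:50], mark, u, random_sets = rs)
  expect_true(pe3$random_ci[1] <= 0.3 && pe3$random_ci[2] >= 0.3)
})

test_that("tissue entropy has the exact closed-form values and bounds", {
  expect_equal(shannon_entropy(rep(1, 8)), 3)        # uniform over 8: 3 bits
  expect_equal(shannon_entropy(c(0, 0, 5, 0)), 0)    # single tissue
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1)
  expect_true(is.na(shannon_entropy(c(0, 0, 0))))
  expect_error(shannon_entropy(c(-1, 2)), "non-negative")
  # permutation invariance and bounds
  x <- c(4, 1, 0, 7, 2, 2, 0, 1)
  expect_equal(shannon_entropy(x), shannon_entropy(rev(x)))
  expect_true(shannon_entropy(x) >= 0 && shannon_entropy(x) <= 3)
  # matrix input: per-column entropies
  m <- cbind(a = rep(1, 4), b = c(1, 0, 0, 0))
  expect_equal(shannon_entropy(m), c(a = 2, b = 0))
})

test_that("size-matched subsets apply the inclusive length window", {
  lengths <- c(g1 = 1250, g2 = 1000, g3 = 1100, g4 = 1400, g5 = 1401)
  out <- matched_size_subset(list(s = names(lengths)), lengths)
  expect_setequal(out$s, c("g1", "g3", "g4"))
  expect_true(all(out$s %in% names(lengths)))
  expect_warning(matched_size_subset(list(s = "g2"), lengths), "empty")
})

test_that("in-silico fragmentation conserves counts and fragment arithmetic", {
  # a 1,800 bp gene yields 6-7 fragments at the default 250-300 bp range
  set.seed(12)
  n_frags <- replicate(50, length(dielvar:::fragment_lengths(1800)))
  expect_true(all(n_frags %in% 6:7))
  lens <- dielvar:::fragment_lengths(1800)
  expect_equal(sum(lens), 1800)
  expect_true(all(lens >= 250))

  st <- sim_one_tp(seed = 5)
  len <- st$ds$gene_lengths
  cand <- names(len)[len >= 1500 & len <= 2500][1:12]
  fc <- fragmentation_control(st$ds$counts[[1]], len, cand, seed = 3)
  # multinomial conservation: fragment counts sum to the parent count
  for (g in cand) {
    fr <- fc$fragment_counts[startsWith(rownames(fc$fragment_counts),
                                        paste0(g, "_frag")), , drop = FALSE]
    expect_equal(unname(colSums(fr)), unname(round(st$ds$counts[[1]][g, ])))
  }
  expect_true(all(fc$fragments$parent %in% cand))
  expect_true(is.finite(fc$concordance))
  expect_error(fragmentation_control(st$ds$counts[[1]], len,
                                     names(len)[len < 400][1]), "too short")
})
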