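#' Compare a numeric gene feature between two gene sets
#'
#' Two-sided Wilcoxon rank-sum comparison of a feature (length, intron
#' count, TF count, entropy, ...) between two gene sets, optionally with a
#' pointwise 95% envelope of the feature's median across random reference
#' sets.
#'
#' @param set_a,set_b character vectors of gene IDs.
#' @param feature named numeric vector of per-gene feature values.
#' @param random_sets optional list of gene sets (e.g. from
#'   [sample_random_sets()]) used to build the envelope.
#' @return list with `statistic`, `p`, per-set medians, and (when random
#'   sets are given) `random_envelope` = 2.5/97.5 percentiles of the
#'   random-set medians.
#' @export
compare_feature <- function(set_a, set_b, feature, random_sets = NULL) {
  if (!length(set_a) || !length(set_b)) stop("both sets must be non-empty")
  xa <- feature[intersect(set_a, names(feature))]
  xb <- feature[intersect(set_b, names(feature))]
  xa <- xa[is.finite(xa)]; xb <- xb[is.finite(xb)]
  if (!length(xa) || !length(xb)) stop("no finite feature values in a set")
  wt <- suppressWarnings(stats::wilcox.test(xa, xb))
  out <- list(statistic = unname(wt$statistic), p = wt$p.value,
              median_a = stats::median(xa), median_b = stats::median(xb))
  if (!is.null(random_sets)) {
    med <- vapply(random_sets, function(s) {
      v <- feature[intersect(s, names(feature))]
      stats::median(v[is.finite(v)])
    }, numeric(1))
    out$random_envelope <- stats::quantile(med, c(0.025, 0.975), na.rm = TRUE)
  }
  out
}

#' Count the number of TFs targeting each gene
#'
#' Scans per-TF target lists and returns, for every gene in the universe,
#' the number of lists it appears in. Targets outside the universe are
#' ignored with a warning.
#'
#' @param tf_targets named list of character vectors (TF -> target genes).
#' @param universe character vector of gene IDs.
#' @return named integer vector over `universe`.
#' @export
count_tf_per_gene <- function(tf_targets, universe) {
  all_targets <- unlist(tf_targets, use.names = FALSE)
  stray <- setdiff(all_targets, universe)
  if (length(stray)) {
    warning(length(stray), " target gene(s) outside the universe ignored")
  }
  counts <- stats::setNames(integer(length(universe)), universe)
  tab <- table(all_targets[all_targets %in% universe])
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Gene-set overrepresentation by the hypergeometric test
#'
#' One-sided (upper-tail) hypergeometric p-value for the overlap between a
#' query set and one or more annotation sets within a gene universe, with
#' BH adjustment across the batch.
#'
#' @param query character vector of gene IDs (subset of universe).
#' @param annotations named list of gene sets, or a single character vector.
#' @param universe character vector of gene IDs.
#' @return data.frame: set_name, set_size, overlap, expected, fold, p, p_adj.
#' @export
set_overrepresentation <- function(query, annotations, universe) {
  if (!length(universe) || !length(query)) stop("empty universe or query")
  if (!is.list(annotations)) annotations <- list(set = annotations)
  query <- intersect(query, universe)
  N <- length(universe); n <- length(query)
  rows <- lapply(names(annotations), function(nm) {
    ann <- intersect(annotations[[nm]], universe)
    K <- length(ann)
    k <- length(intersect(query, ann))
    expected <- n * K / N
    # P(X >= k) for X ~ Hypergeometric(N, K, n)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, set_size = K, overlap = k, expected = expected,
               fold = ifelse(expected > 0, k / expected, NA_real_), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out
}

#' TF-family enrichment among hit TFs
#'
#' For each TF family, a two-sided Fisher exact test of the 2x2 table
#' [in-family hits, in-family non-hits; out-family hits, out-family
#' non-hits], asking whether TFs whose targets are enriched in a gene set
#' concentrate in particular families.
#'
#' @param hit_tfs character vector of TF IDs flagged as hits.
#' @param tf_families data.frame with columns `tf_id`, `family` covering all
#'   TFs tested.
#' @return data.frame: family, n_tfs, n_hits, odds_ratio, p, p_adj.
#' @export
family_enrichment <- function(hit_tfs, tf_families) {
  if (!all(hit_tfs %in% tf_families$tf_id)) stop("unlabeled TF among hits")
  hit <- tf_families$tf_id %in% hit_tfs
  rows <- lapply(split(seq_len(nrow(tf_families)), tf_families$family),
                 function(idx) {
    infam <- seq_len(nrow(tf_families)) %in% idx
    tab <- matrix(c(sum(infam & hit), sum(infam & !hit),
                    sum(!infam & hit), sum(!infam & !hit)), 2, byrow = TRUE)
    ft <- stats::fisher.test(tab)
    data.frame(family = tf_families$family[idx[1]], n_tfs = sum(infam),
               n_hits = sum(infam & hit),
               odds_ratio = unname(ft$estimate), p = min(1, ft$p.value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Enrichment of a binary mark among a gene set
#'
#' Compares the proportion of marked genes in a query set against the
#' proportion among all genes (chi-square test on the 2x2 table, Yates
#' continuity correction by default, with an automatic Fisher fallback when
#' an expected cell drops below 1), plus the 2.5-97.5 percentile interval of
#' the proportion across random reference sets.
#'
#' @param query character vector of gene IDs.
#' @param mark_set character vector of marked gene IDs.
#' @param universe character vector of all gene IDs.
#' @param random_sets optional list of gene sets for the empirical interval.
#' @param correct apply Yates continuity correction (default TRUE).
#' @return list: prop_query, prop_universe, p, test ("chisq" or "fisher"),
#'   and `random_ci` when random sets are given.
#' @export
presence_enrichment <- function(query, mark_set, universe,
                                random_sets = NULL, correct = TRUE) {
  query <- intersect(query, universe)
  mark_set <- intersect(mark_set, universe)
  if (!length(query)) stop("empty query")
  in_q <- universe %in% query
  in_m <- universe %in% mark_set
  tab <- table(factor(in_q, c(FALSE, TRUE)), factor(in_m, c(FALSE, TRUE)))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) {
    p <- stats::fisher.test(tab)$p.value
    test <- "fisher"
  } else {
    p <- suppressWarnings(stats::chisq.test(tab, correct = correct)$p.value)
    test <- "chisq"
  }
  out <- list(prop_query = mean(universe[in_q] %in% mark_set),
              prop_universe = mean(in_m), p = p, test = test)
  if (!is.null(random_sets)) {
    props <- vapply(random_sets, function(s) mean(s %in% mark_set), numeric(1))
    out$random_ci <- stats::quantile(props, c(0.025, 0.975))
  }
  out
}

#' Shannon entropy of a tissue expression profile
#'
#' H = -sum p_t log2 p_t with p_t the relative expression in tissue t. Low
#' entropy means tissue-restricted expression; a uniform profile over T
#' tissues gives log2(T) bits. All-zero profiles return NA (such genes are
#' filtered out upstream).
#'
#' @param x non-negative numeric vector (one gene across tissues), or a
#'   tissues x genes matrix (entropy per column).
#' @return entropy in bits (vector for matrix input).
#' @export
shannon_entropy <- function(x) {
  if (is.matrix(x)) return(apply(x, 2, shannon_entropy))
  if (any(x < 0)) stop("expression must be non-negative")
  s <- sum(x)
  if (s <= 0) return(NA_real_)
  p <- x / s
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Restrict gene sets to a length window
#'
#' Returns, for each input set, the subset of genes whose length lies inside
#' the window (inclusive). Used to compare feature distributions between
#' size-matched HVG / LVG / random subsets.
#'
#' @param sets named list of gene-ID vectors (or a single vector).
#' @param lengths named numeric vector of gene lengths (bp).
#' @param window inclusive length window (default c(1100, 1400) bp).
#' @return list of subsets (same names); warns on empty results.
#' @export
matched_size_subset <- function(sets, lengths, window = c(1100, 1400)) {
  single <- !is.list(sets)
  if (single) sets <- list(set = sets)
  out <- lapply(sets, function(s) {
    l <- lengths[intersect(s, names(lengths))]
    keep <- names(l)[l >= window[1] & l <= window[2]]
    if (!length(keep)) warning("empty size-matched subset")
    keep
  })
  if (single) out[[1]] else out
}

#' Partition a gene length into contiguous fragments
#'
#' Fragment lengths are drawn uniformly in `frag_range`; the final fragment
#' absorbs the remainder so every fragment is at least the minimum length.
#'
#' @param length_bp gene length (>= 2x the minimum fragment length).
#' @param frag_range fragment length range in bp (default c(250, 300)).
#' @return integer vector of fragment lengths summing to `length_bp`.
#' @keywords internal
fragment_lengths <- function(length_bp, frag_range = c(250, 300)) {
  if (length_bp < 2 * frag_range[1]) stop("gene too short to fragment")
  lens <- integer(0)
  rem <- length_bp
  repeat {
    l <- round(stats::runif(1, frag_range[1], frag_range[2]))
    if (rem - l < frag_range[1]) {
      lens <- c(lens, rem)
      break
    }
    lens <- c(lens, l)
    rem <- rem - l
  }
  lens
}

#' In-silico gene fragmentation control
#'
#' Tests whether gene length artifactually drives variability calls:
#' selected genes are split into ~250-300 bp fragments, each individual's
#' count for the gene is reallocated multinomially across fragments with
#' probabilities proportional to fragment length, and the whole
#' TPM -> CV2 -> trend -> HVG pipeline is rerun with fragments in place of
#' their parent genes. Reports per-fragment corrected CV2 / HVG status and
#' concordance with the parent gene's call.
#'
#' @param counts genes x individuals count matrix (one time-point).
#' @param gene_lengths named vector of gene lengths (bp).
#' @param genes gene IDs to fragment (each >= 2x the minimum fragment
#'   length).
#' @param frag_range fragment length range (default c(250, 300) bp).
#' @param seed integer seed for fragment tiling and count reallocation.
#' @param fdr,min_biol_cv HVG-test settings (defaults 0.10).
#' @return list: `fragments` data.frame (fragment_id, parent, length_bp,
#'   mean_tpm, corrected_cv2, is_hvg, parent_is_hvg, concordant),
#'   `concordance` (proportion of fragments matching the parent call),
#'   `parent_table` and `fragment_table` (full variability tables).
#' @export
fragmentation_control <- function(counts, gene_lengths, genes,
                                  frag_range = c(250, 300), seed = 1L,
                                  fdr = 0.10, min_biol_cv = 0.10) {
  stopifnot(all(genes %in% rownames(counts)))
  if (any(gene_lengths[genes] < 2 * frag_range[1])) stop("gene too short to fragment")
  with_seed(seed, {
    frag_rows <- list(); frag_lens <- numeric(0)
    for (g in genes) {
      fl <- fragment_lengths(gene_lengths[[g]], frag_range)
      ids <- sprintf("%s_frag%02d", g, seq_along(fl))
      prob <- fl / sum(fl)
      mat <- vapply(counts[g, ], function(n) {
        as.numeric(stats::rmultinom(1, size = round(n), prob = prob))
      }, numeric(length(fl)))
      if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(fl))
      rownames(mat) <- ids
      frag_rows[[g]] <- mat
      frag_lens <- c(frag_lens, stats::setNames(fl, ids))
    }
    frag_counts <- do.call(rbind, frag_rows)
    colnames(frag_counts) <- colnames(counts)

    keep <- setdiff(rownames(counts), genes)
    new_counts <- rbind(counts[keep, , drop = FALSE], frag_counts)
    new_lengths <- c(gene_lengths[keep], frag_lens)

    run <- function(cnt, len) {
      tpm <- compute_tpm(cnt, len)
      variability_table(tpm, fdr = fdr, min_biol_cv = min_biol_cv)
    }
    parent_tab <- run(counts, gene_lengths)
    frag_tab <- run(new_counts, new_lengths)

    fr <- frag_tab[grepl("_frag\\d+$", frag_tab$gene_id), , drop = FALSE]
    fr$parent <- sub("_frag\\d+$", "", fr$gene_id)
    parent_hvg <- stats::setNames(parent_tab$is_hvg, parent_tab$gene_id)
    fr$parent_is_hvg <- parent_hvg[fr$parent]
    fr$concordant <- fr$is_hvg == fr$parent_is_hvg
    fragments <- data.frame(
      fragment_id = fr$gene_id, parent = fr$parent,
      length_bp = unname(frag_lens[fr$gene_id]),
      mean_tpm = fr$mean_tpm, corrected_cv2 = fr$corrected_cv2,
      is_hvg = fr$is_hvg, parent_is_hvg = fr$parent_is_hvg,
      concordant = fr$concordant, stringsAsFactors = FALSE)
    list(fragments = fragments,
         concordance = mean(fragments$concordant, na.rm = TRUE),
         parent_table = parent_tab, fragment_table = frag_tab,
         fragment_counts = frag_counts)
  })
}
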