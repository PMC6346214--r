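#' Simulation configuration
#'
#' Describes a synthetic diurnal study: individual seedlings sampled at
#' regular time-points over 24 h, with negative-binomial count noise whose
#' TPM-scale CV2 follows the trend a1/mu + a0 for null genes, and a planted
#' set of highly variable genes whose CV2 is inflated by a multiplier at the
#' time-points where their variability cluster is active.
#'
#' The default design mirrors the study layout: 12 time-points (ZT2-ZT24,
#' every 2 h) x 14 individuals = 168 transcriptomes. Time-points 1-6 are
#' tagged "day", 7-12 "night".
#'
#' @param n_timepoints number of time-points (default 12).
#' @param n_individuals individuals per time-point (default 14; 16 supports
#'   the subsampling saturation analysis).
#' @param n_genes number of genes (default 2000).
#' @param trend_a1,trend_a0 trend parameters CV2 = a1/mu + a0 (defaults 1 and
#'   0.02).
#' @param hvg_fraction fraction of genes planted as highly variable
#'   (default 0.10).
#' @param hvg_cv2_multiplier fold excess over the trend for planted HVGs at
#'   active time-points (default 4, must be > 1).
#' @param cluster_scheme data.frame with columns `cluster`, `proportion`,
#'   `first`, `last` (active time-point range) and optional `multiplier`
#'   (NA = use `hvg_cv2_multiplier`). The default plants always-, day- and
#'   night-variable genes in proportions echoing the observed cluster sizes.
#' @param profile_fractions named numeric vector (`flat`, `day`, `night`)
#'   giving the mix of mean-expression profile families.
#' @param profile_amplitude relative amplitude of the sinusoidal diurnal mean
#'   profiles (default 0.5).
#' @param mean_range log-uniform range of baseline relative expression;
#'   values are rescaled per time-point so TPMs total one million.
#' @param library_size expected total counts per individual (default 5e6).
#' @param library_cv coefficient of variation of the log-normal library-size
#'   distribution (default 0.10).
#' @param length_meanlog,length_sdlog log-normal parameters for gene lengths
#'   in bp (defaults log(2000) and 0.5, clipped to [200, 10000]).
#' @param seed integer seed; identical seed and config give bit-identical
#'   output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_timepoints = 12, n_individuals = 14, n_genes = 2000,
                       trend_a1 = 1, trend_a0 = 0.02,
                       hvg_fraction = 0.10, hvg_cv2_multiplier = 4,
                       cluster_scheme = NULL,
                       profile_fractions = c(flat = 0.5, day = 0.25, night = 0.25),
                       profile_amplitude = 0.5,
                       mean_range = c(5, 500),
                       library_size = 5e6, library_cv = 0.10,
                       length_meanlog = log(2000), length_sdlog = 0.5,
                       seed = 1L) {
  if (n_timepoints < 1 || n_individuals < 2 || n_genes < 1) {
    stop("non-positive or degenerate design dimensions")
  }
  if (hvg_fraction < 0 || hvg_fraction > 1) stop("hvg_fraction must be in [0, 1]")
  if (hvg_cv2_multiplier <= 1) stop("hvg_cv2_multiplier must exceed 1")
  if (trend_a1 <= 0 || trend_a0 < 0) stop("trend parameters out of range")
  if (any(mean_range <= 0) || library_size <= 0) stop("means and library size must be positive")
  if (is.null(cluster_scheme)) {
    half <- ceiling(n_timepoints / 2)
    cluster_scheme <- if (n_timepoints >= 2) {
      data.frame(
        cluster = c("always", "day", "night"),
        proportion = c(0.40, 0.15, 0.45),
        first = c(1L, 1L, half + 1L),
        last = c(n_timepoints, half, n_timepoints),
        multiplier = NA_real_,
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(cluster = "always", proportion = 1, first = 1L, last = 1L,
                 multiplier = NA_real_, stringsAsFactors = FALSE)
    }
  }
  if (any(cluster_scheme$first < 1) || any(cluster_scheme$last > n_timepoints) ||
      any(cluster_scheme$first > cluster_scheme$last)) {
    stop("cluster activity masks must lie within the configured time-points")
  }
  structure(list(
    n_timepoints = as.integer(n_timepoints),
    n_individuals = as.integer(n_individuals),
    n_genes = as.integer(n_genes),
    trend_a1 = trend_a1, trend_a0 = trend_a0,
    hvg_fraction = hvg_fraction,
    hvg_cv2_multiplier = hvg_cv2_multiplier,
    cluster_scheme = cluster_scheme,
    profile_fractions = profile_fractions / sum(profile_fractions),
    profile_amplitude = profile_amplitude,
    mean_range = mean_range,
    library_size = library_size, library_cv = library_cv,
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    seed = as.integer(seed)
  ), class = "sim_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic diurnal expression dataset
#'
#' Draws per-individual counts from a negative binomial whose mean follows
#' each gene's diurnal mean profile scaled to the individual's library size,
#' and whose dispersion is chosen so that the expected CV2 of the derived TPM
#' equals trend(mu) for null genes and multiplier x trend(mu) for planted
#' HVGs at their active time-points. The per-gene NB size is obtained by
#' inverting CV2 = 1/mu_count + 1/size at the count scale (the Poisson
#' sampling term plus the overdispersion term); when the target CV2 is below
#' the Poisson floor 1/mu_count the gene falls back to Poisson sampling.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (named list of count matrices, one per
#'   time-point, genes x individuals), `gene_lengths` (named vector, bp),
#'   `truth` (list: `genes` data.frame with is_planted_hvg / cluster /
#'   profile_class, `active` mask matrix, `true_mean` and `true_cv2`
#'   genes x time-points matrices at TPM scale, `phase` per time-point),
#'   and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    G <- config$n_genes; TP <- config$n_timepoints; M <- config$n_individuals
    gene_ids <- sprintf("G%05d", seq_len(G))
    tp_hours <- 2 * seq_len(TP)
    tp_labels <- paste0("ZT", tp_hours)
    half <- ceiling(TP / 2)
    phase <- rep(c("day", "night"), c(half, TP - half))

    base <- 10^stats::runif(G, log10(config$mean_range[1]), log10(config$mean_range[2]))
    pclass <- sample(names(config$profile_fractions), G, replace = TRUE,
                     prob = config$profile_fractions)
    peak <- c(flat = NA_real_, day = 6, night = 18)[pclass]
    mu <- matrix(base, G, TP)
    mod <- ifelse(is.na(peak), 0, 1)
    for (t in seq_len(TP)) {
      mu[, t] <- base * (1 + mod * config$profile_amplitude *
                           cos(2 * pi * (tp_hours[t] - ifelse(is.na(peak), 0, peak)) / 24))
    }
    mu <- sweep(mu, 2, colSums(mu), "/") * 1e6  # TPM scale per time-point
    dimnames(mu) <- list(gene_ids, tp_labels)

    n_hvg <- round(config$hvg_fraction * G)
    planted <- rep(FALSE, G)
    cluster <- rep(NA_character_, G)
    active <- matrix(FALSE, G, TP, dimnames = list(gene_ids, tp_labels))
    mult <- matrix(1, G, TP)
    if (n_hvg > 0) {
      idx <- sample.int(G, n_hvg)
      planted[idx] <- TRUE
      cs <- config$cluster_scheme
      assign_cl <- sample(cs$cluster, n_hvg, replace = TRUE, prob = cs$proportion)
      cluster[idx] <- assign_cl
      for (k in seq_len(nrow(cs))) {
        rows <- idx[assign_cl == cs$cluster[k]]
        cols <- cs$first[k]:cs$last[k]
        active[rows, cols] <- TRUE
        mk <- cs$multiplier[k]
        if (is.na(mk)) mk <- config$hvg_cv2_multiplier
        mult[rows, cols] <- mk
      }
    }
    trend <- config$trend_a1 / mu + config$trend_a0
    true_cv2 <- trend * mult

    lengths <- round(pmin(pmax(
      stats::rlnorm(G, config$length_meanlog, config$length_sdlog), 200), 10000))
    names(lengths) <- gene_ids

    sdlog <- sqrt(log(1 + config$library_cv^2))
    counts <- vector("list", TP)
    names(counts) <- tp_labels
    for (t in seq_len(TP)) {
      w <- mu[, t] * lengths
      w <- w / sum(w)
      lib <- stats::rlnorm(M, log(config$library_size) - sdlog^2 / 2, sdlog)
      cmat <- matrix(0, G, M, dimnames = list(
        gene_ids, sprintf("%s_ind%02d", tp_labels[t], seq_len(M))))
      for (s in seq_len(M)) {
        mu_c <- w * lib[s]
        tau <- true_cv2[, t]
        pois <- tau <= 1 / mu_c * (1 + 1e-6)
        size <- ifelse(pois, Inf, 1 / (tau - 1 / mu_c))
        x <- numeric(G)
        x[pois] <- stats::rpois(sum(pois), mu_c[pois])
        x[!pois] <- stats::rnbinom(sum(!pois), mu = mu_c[!pois], size = size[!pois])
        cmat[, s] <- x
      }
      counts[[t]] <- cmat
    }

    truth <- list(
      genes = data.frame(gene_id = gene_ids, is_planted_hvg = planted,
                         cluster = cluster, profile_class = pclass,
                         length_bp = unname(lengths),
                         stringsAsFactors = FALSE),
      active = active, true_mean = mu, true_cv2 = true_cv2, phase = phase
    )
    list(counts = counts, gene_lengths = lengths, truth = truth, config = config)
  })
}

#' Generate per-gene features and annotation sets with planted associations
#'
#' Samples gene length, intron count, TF-target lists and chromatin-mark
#' gene sets so that planted HVGs differ from null genes by the stated
#' effect sizes; with all effects zero, planted and null genes are
#' exchangeable.
#'
#' @param truth the `truth` element of a [generate_dataset()] result.
#' @param length_effect relative length shift for planted HVGs (e.g. -0.3 for
#'   30% shorter; must exceed -1).
#' @param intron_effect relative shift of the mean intron count (> -1).
#' @param tf_effect relative increase in per-TF targeting probability for
#'   planted HVGs (> -1; default 1 doubles it).
#' @param marks data.frame with `mark`, `base_freq`, `hvg_mult` columns; the
#'   default plants one 2x-enriched, one neutral and one depleted mark.
#' @param n_tfs number of simulated TFs (default 50).
#' @param tf_base_prob baseline probability a TF targets a gene (default 0.05).
#' @param n_families number of TF families (default 8).
#' @param intron_mean baseline mean intron count (default 4).
#' @param seed integer seed.
#' @return list with `features` (data.frame gene_id / length_bp / n_introns /
#'   n_tfs), `tf_targets` (named list of target-gene sets), `marks` (named
#'   list of marked-gene sets), `tf_families` (data.frame tf_id / family)
#'   and `universe`.
#' @export
generate_gene_features <- function(truth,
                                   length_effect = -0.3, intron_effect = -0.4,
                                   tf_effect = 1,
                                   marks = data.frame(
                                     mark = c("mark_A", "mark_B", "mark_C"),
                                     base_freq = c(0.20, 0.40, 0.30),
                                     hvg_mult = c(2, 1, 0.5),
                                     stringsAsFactors = FALSE),
                                   n_tfs = 50, tf_base_prob = 0.05,
                                   n_families = 8, intron_mean = 4,
                                   seed = 1L) {
  if (length_effect <= -1 || intron_effect <= -1 || tf_effect <= -1) {
    stop("relative effects must exceed -1")
  }
  if (any(marks$hvg_mult < 0)) stop("mark multipliers must be non-negative")
  with_seed(seed, {
    g <- truth$genes
    G <- nrow(g)
    hvg <- g$is_planted_hvg

    len <- g$length_bp
    len[hvg] <- pmax(50, round(len[hvg] * (1 + length_effect)))

    introns <- stats::rpois(G, intron_mean * ifelse(hvg, 1 + intron_effect, 1))

    tf_ids <- sprintf("TF%03d", seq_len(n_tfs))
    p0 <- pmin(tf_base_prob * ifelse(hvg, 1 + tf_effect, 1), 1)
    memb <- matrix(stats::rbinom(G * n_tfs, 1, rep(p0, n_tfs)) == 1, G, n_tfs)
    tf_targets <- stats::setNames(
      lapply(seq_len(n_tfs), function(j) g$gene_id[memb[, j]]), tf_ids)

    mark_sets <- stats::setNames(vector("list", nrow(marks)), marks$mark)
    for (k in seq_len(nrow(marks))) {
      pm <- pmin(marks$base_freq[k] * ifelse(hvg, marks$hvg_mult[k], 1), 0.95)
      mark_sets[[k]] <- g$gene_id[stats::rbinom(G, 1, pm) == 1]
    }

    fam <- paste0("family_", 1 + (seq_len(n_tfs) - 1) %% n_families)

    list(
      features = data.frame(gene_id = g$gene_id, length_bp = len,
                            n_introns = introns, n_tfs = rowSums(memb),
                            stringsAsFactors = FALSE),
      tf_targets = tf_targets,
      marks = mark_sets,
      tf_families = data.frame(tf_id = tf_ids, family = fam,
                               stringsAsFactors = FALSE),
      universe = g$gene_id
    )
  })
}

#' Generate a tissue x gene expression table
#'
#' Draws per-tissue relative expression from a gamma profile family; when
#' `restriction_shape` is smaller than `null_shape`, planted HVGs get more
#' tissue-restricted (lower-entropy) profiles.
#'
#' @param truth the `truth` element of a [generate_dataset()] result.
#' @param n_tissues number of tissues (>= 2, default 8).
#' @param null_shape gamma shape for null-gene tissue profiles (default 5).
#' @param restriction_shape gamma shape for planted HVGs (default 0.5; set
#'   equal to `null_shape` for no planted restriction).
#' @param seed integer seed.
#' @return numeric matrix, tissues x genes, non-negative.
#' @export
generate_tissue_table <- function(truth, n_tissues = 8, null_shape = 5,
                                  restriction_shape = 0.5, seed = 1L) {
  if (n_tissues < 2) stop("need at least 2 tissues")
  with_seed(seed, {
    g <- truth$genes
    shape <- ifelse(g$is_planted_hvg, restriction_shape, null_shape)
    tab <- vapply(seq_len(nrow(g)), function(i) {
      stats::rgamma(n_tissues, shape = shape[i], rate = 1)
    }, numeric(n_tissues))
    dimnames(tab) <- list(paste0("tissue_", seq_len(n_tissues)), g$gene_id)
    tab
  })
}
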