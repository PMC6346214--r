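#!/usr/bin/env Rscript

# Stage 3 — time-course structure of variability.
#
# From the stage-2 results: distribution of per-gene HVG time-point counts,
# pairwise sharing between time-points, day/night block averages, 1-Pearson
# complete-linkage clustering of corrected-CV2 profiles, the correlation
# between expression and variability profiles, and the seedling-subsampling
# saturation analysis on a 16-individual time-point.

suppressPackageStartupMessages(library(dielvar))

indir <- "results/01_synthetic"
out <- "results/03_timecourse"
if (!dir.exists(indir)) stop("run analysis/01_simulate.R first")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
wt <- function(x, f) write.table(x, file.path(out, f), sep = "\t",
                                 quote = FALSE, row.names = FALSE)

files <- list.files(indir, pattern = "^counts_ZT\\d+\\.tsv$", full.names = TRUE)
tps <- sub("^counts_(ZT\\d+)\\.tsv$", "\\1", basename(files))
ord <- order(as.integer(sub("ZT", "", tps)))
counts <- setNames(lapply(files[ord], read_expression_tsv), tps[ord])
gm <- read_gene_models_tsv(file.path(indir, "gene_models.tsv"))
lengths <- setNames(gm$length_bp, gm$gene_id)

res <- run_pipeline(counts, lengths, unit = "counts",
                    config = run_config(seed = 1L))
tc <- res$timecourse

hist <- timepoint_count_distribution(tc$hvg)
wt(data.frame(n_timepoints = seq_along(hist), n_genes = hist),
   "hvg_timepoint_histogram.tsv")
message(sprintf("genes HVG at >= 1 time-point: %d; at all 12: %d",
                sum(hist), hist[length(hist)]))

wt(data.frame(timepoint = rownames(res$sharing), round(res$sharing, 2),
              check.names = FALSE), "sharing_matrix.tsv")
dn <- res$day_night
message(sprintf(paste("mean HVG sharing (ZT12 excluded): within day %.1f%%,",
                      "within night %.1f%%, between phases %.1f%%"),
                dn[["within_day"]], dn[["within_night"]], dn[["between"]]))
wt(data.frame(block = names(dn), mean_sharing_pct = round(unname(dn), 2)),
   "day_night_summary.tsv")

lab <- res$clusters$labels
wt(data.frame(gene_id = names(lab), cluster = unname(lab)), "clusters.tsv")
message("cluster sizes (corrected-CV2 profiles of union HVGs, k = 4): ",
        paste(table(lab), collapse = " / "))

pc <- res$profile_cor
wt(pc, "profile_correlation.tsv")
sig <- mean(pc$class %in% c("significant_positive", "significant_negative"),
            na.rm = TRUE)
message(sprintf(paste("expression-variability profile correlation:",
                      "%.0f%% of union HVGs significant at P <= 0.05"),
                100 * sig))

# saturation: how many seedlings are enough? (16-individual time-point)
ds16 <- generate_dataset(sim_config(n_timepoints = 1, n_individuals = 16,
                                    seed = 16L))
tpm16 <- compute_tpm(ds16$counts[[1]], ds16$gene_lengths)
sat <- subsample_stability(tpm16, ds16$gene_lengths, sizes = 6:15,
                           n_draws = 20, seed = 1L)
wt(sat, "subsample_saturation.tsv")
message("corrected-CV2 correlation vs 16 individuals by subset size:")
message(paste(sprintf("  %d: %.3f", sat$size, sat$mean_cor), collapse = "\n"))
message("written to ", out)
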