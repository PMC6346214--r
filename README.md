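# dielvar

Inter-individual gene expression variability across a diurnal time course.

Two genetically identical individuals grown in the same conditions do not
express their genes at identical levels. `dielvar` quantifies this
inter-individual variability from per-time-point expression matrices
(genes × individuals, counts or TPM), identifies *highly variable genes*
(HVGs) per time-point, tracks how variability is structured across a
day/night cycle, and asks what distinguishes variable genes — gene length,
intron count, transcription-factor targeting, chromatin marks, tissue
specificity. It is aimed at the bulk "one individual = one library" design
(e.g. single plant seedlings harvested every 2 h over 24 h, 14 individuals
per time-point), and ships a fully specified synthetic-data generator so
the entire pipeline is testable against known ground truth.

## The statistic

For each gene at each time-point, variability across the m individuals is
the squared coefficient of variation,

    CV² = s² / μ²

with s² the unbiased sample variance and μ the mean TPM. Because CV² falls
with expression level, a mean–variability trend

    CV²(μ) = a₁/μ + α₀

is fitted per time-point by a gamma-family GLM with identity link on the
filtered transcriptome. Each gene's variability is then expressed relative
to genes of the same expression level as the **corrected CV²**,

    corrected CV² = log₂( CV² / CV²trend(μ) )

(0 = on trend, 1 = twice as variable). A gene is called an HVG when its CV²
significantly exceeds the trend plus a minimal biological CV of 10%: with
minBiolDisp = 0.10², cv2th = α₀ + minBiolDisp + α₀·minBiolDisp, the
statistic

    (m−1) · μ² · CV² / [ (μ·a₁ + μ²·cv2th) / (1 + cv2th/m) ]

is referred to the upper tail of χ²(m−1) and adjusted by Benjamini–Hochberg,
calling HVGs at FDR < 10%. Before testing, genes are filtered on four rules:
mean ≥ 5 TPM over all loaded samples, length ≥ 150 bp, fewer than 5
zero-TPM individuals at the time-point, and mean ≥ 5 TPM at the time-point.

Downstream, the per-time-point tables are assembled into a time course:
HVG sharing between time-points, day/night block averages, hierarchical
clustering of corrected-CV² profiles (1 − Pearson distance, complete
linkage, k = 4), correlation between expression and variability profiles,
lowly-variable (bottom-n corrected CV²) and random size-matched reference
sets, and feature/annotation enrichment (Wilcoxon, hypergeometric, Fisher,
chi-square) with empirical random-set envelopes.

## Worked example

The analysis is organised as numbered drivers under `analysis/`, each a thin
script over the package functions:

```sh
Rscript analysis/01_simulate.R     # synthetic 12 ZT x 14 individuals x 2,000 genes
Rscript analysis/02_hvg.R          # filters, trend fits, HVG calls per ZT
Rscript analysis/03_timecourse.R   # sharing, clustering, saturation
Rscript analysis/04_enrichment.R   # features, TF targets, marks, entropy
```

Stage 2 prints, for the default simulation (10% planted HVGs at 4× the
trend CV², organised into always/day/night-variable clusters):

```
HVGs per time-point:
  ZT2: 56
  ...
  ZT16: 90
union HVG set: 196 genes (9.8% of tested transcriptome)
  trend ZT2: CV2 = 1.116/mu + 0.0240
```

i.e. more HVGs are called during the night (the night-variable cluster is
the largest planted class), the union HVG set recovers essentially all 200
planted genes, and the fitted trends sit near the generating parameters
(a₁ = 1, α₀ = 0.02). Stage 3 prints the day/night structure and the
seedling-saturation analysis:

```
mean HVG sharing (ZT12 excluded): within day 55.4%, within night 53.2%, between phases 28.1%
corrected-CV2 correlation vs 16 individuals by subset size:
  6: 0.641
  ...
  12: 0.882
  15: 0.971
```

— time-points within a phase share far more HVGs than across phases, and
corrected CV² stabilises as individuals are added. Stage 4 recovers the
planted gene-feature associations (HVGs shorter: median 1,548 vs 1,984 bp,
Wilcoxon P ≈ 9e−12; fewer introns; more targeting TFs; the planted 2×
chromatin mark at P ≈ 7e−15; lower tissue entropy) and runs the
fragmentation control (27 genes of 1.5–2.5 kb split into ~250–300 bp
fragments; 99.5% of fragments keep their parent's HVG status, showing the
length association is not a quantification artifact).

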