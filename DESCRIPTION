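Package: dielvar
Title: Inter-Individual Gene Expression Variability Across a Diurnal Time Course
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and characterisation of inter-individual gene expression
    variability from per-time-point expression matrices. Fits the CV2-mean
    trend with a gamma-family GLM, tests genes for excess variability with a
    chi-square overdispersion statistic under Benjamini-Hochberg FDR control,
    computes corrected CV2 (log2 ratio to trend), assembles diurnal time-course
    variability profiles (membership, sharing, hierarchical clustering), and
    compares highly variable genes against lowly variable and random reference
    sets for genomic and epigenomic feature enrichment. Includes a
    negative-binomial synthetic-data generator with planted highly variable
    genes so every stage is verifiable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    rtracklayer,
    BiocGenerics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
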