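#' Read / write expression matrices as TSV
#'
#' Tab-separated, genes in rows with a leading `gene_id` column, one column
#' per individual.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("negative expression values")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop("gene and sample IDs must be unique")
  }
  m
}

#' @rdname read_expression_tsv
#' @param mat numeric matrix, genes x samples.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated gene IDs.
#'
#' @param path file path.
#' @return named list of character vectors; descriptions kept in the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  attr(sets, "descriptions") <- vapply(parts, `[[`, character(1), 2)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector (defaults to set names).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a flat TSV
#'
#' Expects columns `gene_id`, `length_bp`, `n_introns`.
#'
#' @param path file path.
#' @return data.frame with those columns.
#' @export
read_gene_models_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "length_bp", "n_introns")
  if (!all(need %in% names(df))) {
    stop("gene model TSV needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$length_bp <= 0) || any(df$n_introns < 0)) {
    stop("invalid gene model values")
  }
  df[need]
}

#' Derive gene length and intron count from a GFF3 file
#'
#' For each gene, exons of its representative (longest-spanning) transcript
#' are summed to give the length, and the intron count is the number of
#' exons minus one. Requires the rtracklayer package.
#'
#' @param path GFF3 file.
#' @return data.frame: gene_id, length_bp, n_introns.
#' @export
gene_models_from_gff <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required to parse GFF3")
  }
  gr <- rtracklayer::import(path)
  ex <- gr[gr$type == "exon"]
  tx_parent <- vapply(ex$Parent, `[[`, character(1), 1)
  mrna <- gr[gr$type %in% c("mRNA", "transcript")]
  mrna_gene <- sub("^gene:", "", vapply(mrna$Parent, `[[`, character(1), 1))
  names(mrna_gene) <- mrna$ID
  span <- stats::setNames(BiocGenerics::width(mrna), mrna$ID)
  rep_tx <- vapply(split(names(span), mrna_gene[names(span)]),
                   function(tx) tx[which.max(span[tx])], character(1))
  rows <- lapply(names(rep_tx), function(g) {
    exi <- ex[tx_parent == rep_tx[[g]]]
    data.frame(gene_id = g, length_bp = sum(BiocGenerics::width(exi)),
               n_introns = max(length(exi) - 1L, 0L), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a synthetic dataset to disk
#'
#' One TSV count matrix per time-point, a gene-model TSV, the planted truth
#' as TSV plus a YAML sidecar with the generator configuration, and the
#' annotation sets (when given) as GMT.
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @param features optional [generate_gene_features()] result.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, features = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tp in names(dataset$counts)) {
    write_expression_tsv(dataset$counts[[tp]],
                         file.path(dir, paste0("counts_", tp, ".tsv")))
  }
  gm <- data.frame(gene_id = names(dataset$gene_lengths),
                   length_bp = unname(dataset$gene_lengths),
                   n_introns = NA_integer_)
  if (!is.null(features)) {
    gm <- features$features[, c("gene_id", "length_bp", "n_introns")]
    write_gmt(c(features$tf_targets, features$marks),
              file.path(dir, "annotation_sets.gmt"))
    utils::write.table(features$tf_families,
                       file.path(dir, "tf_families.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(gm, file.path(dir, "gene_models.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- dataset$config
  cfg$cluster_scheme <- as.list(cfg$cluster_scheme)
  yaml::write_yaml(unclass(cfg), file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
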