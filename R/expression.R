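#' Expression matrix container
#'
#' Wraps a samples x genes numeric matrix together with its processing stage.
#' The stage records the units of the values: `"counts"` (raw read counts),
#' `"tpm"` (transcripts per million, each non-degenerate sample summing to
#' 1e6) or `"log"` (log-transformed TPM).
#'
#' @param values Numeric matrix, rows = samples, columns = genes.
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to the matrix rownames.
#' @param gene_ids Character vector of unique gene identifiers; defaults to
#'   the matrix colnames.
#' @param stage One of `"counts"`, `"tpm"`, `"log"`.
#' @return An object of class `expr_matrix`: the numeric matrix with
#'   dimnames set and a `stage` attribute.
#' @export
expression_matrix <- function(values, sample_ids = rownames(values),
                              gene_ids = colnames(values),
                              stage = c("counts", "tpm", "log")) {
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if (is.null(sample_ids) || is.null(gene_ids))
    stopf("sample and gene identifiers are required (rownames/colnames or explicit arguments)")
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (length(sample_ids) != nrow(values))
    stopf("length of sample_ids (%d) != number of rows (%d)", length(sample_ids), nrow(values))
  if (length(gene_ids) != ncol(values))
    stopf("length of gene_ids (%d) != number of columns (%d)", length(gene_ids), ncol(values))
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) stopf("duplicated sample ids: %s", paste(dup_s, collapse = ", "))
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) stopf("duplicated gene ids: %s", paste(dup_g, collapse = ", "))
  if (any(!is.finite(values))) stopf("expression values must be finite")
  if (stage %in% c("counts", "tpm") && any(values < 0))
    stopf("stage '%s' values must be non-negative", stage)
  if (stage == "tpm") {
    rs <- rowSums(values)
    bad <- which(rs > 0 & abs(rs - 1e6) > 1e-6 * 1e6)
    if (length(bad))
      stopf("TPM rows must sum to 1e6 (off for samples: %s)",
            paste(utils::head(sample_ids[bad], 5), collapse = ", "))
  }
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(values, stage = stage, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d samples x %d genes, stage = %s\n",
              nrow(x), ncol(x), attr(x, "stage")))
  invisible(x)
}

expr_stage <- function(x) attr(x, "stage") %||% "log"

# Drop the class/stage so downstream numerics see a plain matrix.
as_plain_matrix <- function(x) {
  y <- unclass(x)
  attr(y, "stage") <- NULL
  y
}

#' Label vector for classification
#'
#' @param labels Character (or factor) vector of per-sample class labels.
#' @param label_set Ordered vector of allowed labels; defaults to the sorted
#'   unique labels.
#' @param positive_class Class treated as positive for binary F1/AUC;
#'   defaults to the last element of `label_set`.
#' @return A factor of class `label_vector` with a `positive_class` attribute.
#' @export
label_vector <- function(labels, label_set = NULL, positive_class = NULL) {
  labels <- as.character(labels)
  if (is.null(label_set)) label_set <- sort(unique(labels))
  label_set <- as.character(label_set)
  if (length(label_set) < 2) stopf("label_set must contain at least 2 classes")
  bad <- setdiff(unique(labels), label_set)
  if (length(bad)) stopf("labels outside label_set: %s", paste(bad, collapse = ", "))
  if (is.null(positive_class)) positive_class <- label_set[length(label_set)]
  if (!positive_class %in% label_set) stopf("positive_class '%s' not in label_set", positive_class)
  structure(factor(labels, levels = label_set),
            positive_class = positive_class, class = c("label_vector", "factor"))
}

positive_class <- function(y) attr(y, "positive_class") %||% levels(y)[nlevels(y)]

# Re-wrap a subset of a label_vector, keeping levels and positive class.
subset_labels <- function(y, idx) {
  label_vector(as.character(y)[idx], label_set = levels(y),
               positive_class = positive_class(y))
}

#' Read an expression matrix from a delimited text file
#'
#' The file must carry ids in the first row and first column. Orientation on
#' disk may be either samples-in-rows or genes-in-rows; the returned matrix is
#' always samples x genes.
#'
#' @param path Path to a TSV/CSV file.
#' @param orientation `"samples_by_genes"` (default) if file rows are samples,
#'   `"genes_by_samples"` if file rows are genes.
#' @param delimiter Field separator, default tab.
#' @param stage Processing stage of the stored values (see
#'   [expression_matrix()]).
#' @return An `expr_matrix`.
#' @export
read_expression <- function(path, orientation = c("samples_by_genes", "genes_by_samples"),
                            delimiter = "\t", stage = "log") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stopf("expression file needs a header plus at least one data row: %s", path)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths[-1])) > 1)
    stopf("ragged rows in %s: widths %s", path, paste(unique(widths[-1]), collapse = ", "))
  header <- fields[[1]]
  # Header may or may not include a leading cell for the id column.
  col_ids <- if (length(header) == widths[2]) header[-1] else header
  if (length(col_ids) != widths[2] - 1)
    stopf("header width does not match data rows in %s", path)
  row_ids <- vapply(fields[-1], `[[`, "", 1L)
  cells <- lapply(fields[-1], function(f) f[-1])
  num <- suppressWarnings(lapply(cells, as.numeric))
  for (i in seq_along(num)) {
    bad <- which(is.na(num[[i]]) & !is.na(cells[[i]]) & cells[[i]] != "NA")
    if (length(bad))
      stopf("non-numeric value '%s' at data row %d, column %d of %s",
            cells[[i]][bad[1]], i, bad[1], path)
  }
  values <- do.call(rbind, num)
  rownames(values) <- row_ids
  colnames(values) <- col_ids
  if (orientation == "genes_by_samples") values <- t(values)
  expression_matrix(values, stage = stage)
}

#' Write an expression matrix as TSV
#'
#' @param x An `expr_matrix`.
#' @param path Output path.
#' @param delimiter Field separator, default tab.
#' @export
write_expression <- function(x, path, delimiter = "\t") {
  df <- data.frame(sample_id = rownames(x), as_plain_matrix(x), check.names = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column sample/label table
#'
#' @param path TSV with columns `sample_id`, `label` (header required).
#' @param positive_class Optional positive class (see [label_vector()]).
#' @return A named `label_vector` (names = sample ids).
#' @export
read_labels <- function(path, positive_class = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("label file must have two columns (sample_id, label)")
  y <- label_vector(df[[2]], positive_class = positive_class)
  names(y) <- as.character(df[[1]])
  y
}

#' Read a two-column gene-length table
#'
#' @param path TSV with columns `gene_id`, `length_bases` (header required).
#' @return Named numeric vector of lengths in bases.
#' @export
read_gene_lengths <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("gene length file must have two columns (gene_id, length_bases)")
  len <- as.numeric(df[[2]])
  names(len) <- as.character(df[[1]])
  len
}

#' TPM normalization
#'
#' Converts raw read counts to transcripts per million: per sample, each
#' gene's count is divided by its length (length-rate), and rates are scaled
#' to sum to 1e6. Samples with all-zero counts stay all-zero (with a warning).
#'
#' @param counts An `expr_matrix` with stage `"counts"`.
#' @param gene_lengths Named numeric vector of positive gene lengths in
#'   bases covering every gene in `counts`.
#' @return An `expr_matrix` with stage `"tpm"`.
#' @export
normalize_tpm <- function(counts, gene_lengths) {
  if (expr_stage(counts) != "counts") stopf("normalize_tpm expects stage 'counts'")
  if (any(counts < 0)) stopf("negative counts are not allowed")
  gid <- colnames(counts)
  if (is.null(names(gene_lengths))) {
    if (length(gene_lengths) != ncol(counts))
      stopf("unnamed gene_lengths must have one entry per gene (%d != %d)",
            length(gene_lengths), ncol(counts))
    names(gene_lengths) <- gid
  }
  missing <- setdiff(gid, names(gene_lengths))
  if (length(missing))
    stopf("missing gene lengths for: %s", paste(utils::head(missing, 5), collapse = ", "))
  len <- gene_lengths[gid]
  if (any(!is.finite(len) | len <= 0)) stopf("gene lengths must be positive and finite")
  rate <- sweep(as_plain_matrix(counts), 2, len, "/")
  tot <- rowSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warnf("%d sample(s) with all-zero counts left as all-zero TPM rows", sum(zero))
    tot[zero] <- 1  # avoid 0/0; rows are all zero anyway
  }
  tpm <- rate / tot * 1e6
  expression_matrix(tpm, rownames(counts), gid, stage = "tpm")
}

#' Log transform of TPM values
#'
#' Elementwise `log(x + pseudocount)` in the chosen base; the default
#' `log2(x + 1)` is the dominant RNA-seq convention.
#'
#' @param tpm An `expr_matrix` with stage `"tpm"`.
#' @param base Logarithm base, default 2.
#' @param pseudocount Added before taking the log, default 1.
#' @return An `expr_matrix` with stage `"log"`.
#' @export
log_transform <- function(tpm, base = 2, pseudocount = 1) {
  if (expr_stage(tpm) != "tpm") stopf("log_transform expects stage 'tpm'")
  if (any(tpm < 0)) stopf("negative values cannot be log-transformed")
  out <- log(as_plain_matrix(tpm) + pseudocount, base = base)
  expression_matrix(out, rownames(tpm), colnames(tpm), stage = "log")
}
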