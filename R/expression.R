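#' Read a gene-by-sample expression matrix from TSV
#'
#' Expected layout: tab-separated, header row of sample ids, first column the
#' gene (or probe) identifier, remaining cells numeric log-scale expression
#' values. Parsing is locale-independent (decimal point). Any non-numeric or
#' missing cell is an error naming its position; ragged rows are an error.
#'
#' @param path path to the TSV file.
#' @return numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns (colnames = sample ids).
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) xmn_abort("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) xmn_abort("expression file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  n_col <- length(header)
  if (n_col < 2L) xmn_abort("expression file needs at least one sample column")
  samples <- header[-1]

  n_row <- length(fields) - 1L
  out <- matrix(NA_real_, n_row, n_col - 1L)
  ids <- character(n_row)
  for (i in seq_len(n_row)) {
    f <- fields[[i + 1L]]
    if (length(f) != n_col) {
      xmn_abort("ragged row ", i + 1L, ": expected ", n_col, " fields, found ", length(f))
    }
    ids[i] <- f[1]
    v <- suppressWarnings(as.numeric(f[-1]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      xmn_abort(
        "non-numeric value '", f[bad[1] + 1L], "' at row ", i + 1L,
        " (gene ", f[1], "), column ", bad[1] + 1L, " (sample ", samples[bad[1]], ")"
      )
    }
    out[i, ] <- v
  }
  dimnames(out) <- list(ids, samples)
  out
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]; values are written with R's full default
#' precision (15 significant digits) so a write/read round trip reproduces
#' them beyond 12 significant digits.
#'
#' @param x numeric gene-by-sample matrix with dimnames.
#' @param path output path.
#' @param id_column header of the first (gene id) column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, id_column = "gene_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE)
  colnames(df) <- c(id_column, colnames(x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-label table
#'
#' TSV with header `sample_id<TAB>label`.
#'
#' @param path path to the labels TSV.
#' @return factor of labels named by sample id; levels are the distinct
#'   classes in order of first appearance.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) xmn_abort("file not found: ", path)
  df <- read.delim(path, colClasses = "character")
  if (ncol(df) < 2L) xmn_abort("label file needs columns sample_id and label")
  if (anyDuplicated(df[[1]])) {
    xmn_abort("duplicate sample id in labels: ", df[[1]][duplicated(df[[1]])][1])
  }
  setNames(factor(df[[2]], levels = unique(df[[2]])), df[[1]])
}

#' Write a sample-label table
#' @param labels factor named by sample id.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  write.table(
    data.frame(sample_id = names(labels), label = as.character(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Aggregate duplicate identifiers by mean
#'
#' Collapses probe-level rows to gene-level rows: every gene's expression is
#' the arithmetic mean over all probe rows mapping to it. Probes without a
#' mapping entry are dropped (a message reports how many); a probe mapped to
#' several genes contributes to each of them (fan-out, also reported).
#' Sample columns and their order are preserved.
#'
#' @param x numeric probe-by-sample matrix.
#' @param mapping data.frame with columns `probe_id`, `gene_id`.
#' @return numeric gene-by-sample matrix.
#' @export
aggregate_duplicates <- function(x, mapping) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  need <- setdiff(c("probe_id", "gene_id"), names(mapping))
  if (length(need)) xmn_abort("mapping misses column(s): ", paste(need, collapse = ", "))
  mapping <- data.frame(
    probe_id = as.character(mapping$probe_id),
    gene_id = as.character(mapping$gene_id), stringsAsFactors = FALSE
  )
  mapping <- unique(mapping)
  mapping <- mapping[mapping$probe_id %in% rownames(x), , drop = FALSE]
  n_unmapped <- sum(!rownames(x) %in% mapping$probe_id)
  if (n_unmapped) message(n_unmapped, " unmapped probe(s) dropped")
  n_fan <- sum(duplicated(mapping$probe_id))
  if (n_fan) message(n_fan, " probe-to-gene assignment(s) beyond the first (fan-out)")
  if (!nrow(mapping)) xmn_abort("no probes could be mapped")

  rows <- x[mapping$probe_id, , drop = FALSE]
  g <- factor(mapping$gene_id, levels = sort(unique(mapping$gene_id)))
  sums <- rowsum(rows, g)
  sums / as.vector(table(g))
}

#' Mean-center expression per gene
#'
#' Subtracts a per-gene mean from every row, the standard preprocessing for
#' relevance propagation (centering reduces relevance absorption at the
#' input). When `means` is supplied (e.g. the training-fold means inside
#' cross-validation) those are used instead of the matrix's own row means, so
#' held-out folds are centered with training statistics only.
#'
#' @param x numeric gene-by-sample matrix.
#' @param means optional named numeric vector of per-gene means to apply.
#' @return centered matrix with attribute `"gene_means"` carrying the means
#'   that were subtracted.
#' @export
mean_center <- function(x, means = NULL) {
  stopifnot(is.matrix(x))
  if (is.null(means)) {
    means <- rowMeans(x)
  } else {
    if (is.null(names(means)) || !all(rownames(x) %in% names(means))) {
      xmn_abort("means must be named and cover every gene in x")
    }
    means <- means[rownames(x)]
  }
  out <- x - means
  attr(out, "gene_means") <- means
  out
}
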