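## Readers and writers for the plain-text interchange formats used by the
## pipeline: counts TSV (first column gene id), sample metadata TSV, 3-column
## weighted edge lists, GMT gene-set collections and one-id-per-line gene
## lists. All tables are tab-separated with a header and no quoting.

write_tsv <- function(df, path) {
  tryCatch(
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) abort("failed to write ", path, ": ", conditionMessage(e))
  )
  invisible(path)
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) abort("file not found: ", path)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

#' Read a gene-by-sample count matrix from TSV
#'
#' The first column holds gene identifiers, remaining columns one sample
#' each, with integer cells.
#'
#' @param path file path.
#' @return Integer matrix with gene row names and sample column names.
#' @export
read_counts_tsv <- function(path) {
  df <- read_tsv(path)
  if (ncol(df) < 2L) abort("counts TSV needs a gene column plus samples: ", path)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) abort("duplicate gene ids in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  if (anyNA(m) || any(m < 0L)) abort("counts must be non-negative integers: ", path)
  rownames(m) <- genes
  m
}

#' Write a count matrix to TSV
#' @param counts integer gene x sample matrix.
#' @param path file path.
#' @export
write_counts_tsv <- function(counts, path) {
  write_tsv(data.frame(gene = rownames(counts), counts, check.names = FALSE), path)
}

#' Read a sample metadata table
#'
#' Expects at least columns `sample`, `condition` (OA / nonOA), `group`
#' (A / B / NA) and `batch`.
#'
#' @param path file path.
#' @return A data.frame.
#' @export
read_metadata_tsv <- function(path) {
  df <- read_tsv(path)
  needed <- c("sample", "condition", "batch")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    abort("metadata TSV missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample)) abort("duplicate sample ids in ", path)
  df
}

#' Read a weighted gene-gene interaction network from an edge-list TSV
#'
#' Three columns: gene_a, gene_b, weight. Self-loops are dropped and
#' duplicate edges collapsed (weights summed).
#'
#' @param path file path.
#' @return An undirected weighted [igraph::graph] with gene-name vertices.
#' @export
read_network_tsv <- function(path) {
  df <- read_tsv(path)
  if (ncol(df) < 2L) abort("edge list needs at least two columns: ", path)
  if (ncol(df) == 2L) df$weight <- 1
  names(df)[1:3] <- c("gene_a", "gene_b", "weight")
  if (any(df$weight <= 0)) abort("edge weights must be positive: ", path)
  g <- igraph::graph_from_data_frame(df[, 1:3], directed = FALSE)
  igraph::simplify(g, edge.attr.comb = list(weight = "sum"))
}

#' Write a network as a 3-column edge-list TSV
#' @param network an igraph object with a `weight` edge attribute.
#' @param path file path.
#' @export
write_network_tsv <- function(network, path) {
  el <- igraph::as_data_frame(network, what = "edges")
  if (is.null(el$weight)) el$weight <- 1
  names(el)[1:2] <- c("gene_a", "gene_b")
  write_tsv(el[, c("gene_a", "gene_b", "weight")], path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated set name,
#' description, then member genes. Members are de-duplicated.
#'
#' @param path file path.
#' @return Named list of character vectors, with a `description` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, 1L) < 3L
  if (any(bad)) abort("GMT line(s) with fewer than 3 fields in ", path)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  attr(sets, "description") <- setNames(
    vapply(fields, `[[`, "", 2L), names(sets))
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path file path.
#' @param descriptions optional named descriptions; defaults to set names.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% nm, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain gene list (one identifier per line)
#' @param path file path.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort("file not found: ", path)
  x <- readLines(path, warn = FALSE)
  unique(trimws(x[nzchar(trimws(x))]))
}

#' Write a plain gene list
#' @param genes character vector.
#' @param path file path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Write a differential-expression table to TSV
#' @param de a `de_result` data.frame from [de_test()].
#' @param path file path.
#' @export
write_de_tsv <- function(de, path) {
  write_tsv(as.data.frame(de), path)
}

#' Read a differential-expression table written by [write_de_tsv()]
#' @param path file path.
#' @return A data.frame with class `de_result`.
#' @export
read_de_tsv <- function(path) {
  df <- read_tsv(path)
  needed <- c("gene", "baseMean", "log2FC", "pvalue", "padj", "is_deg")
  missing <- setdiff(needed, names(df))
  if (length(missing)) abort("DE TSV missing column(s): ",
                             paste(missing, collapse = ", "))
  df$is_deg <- as.logical(df$is_deg)
  class(df) <- c("de_result", class(df))
  df
}
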