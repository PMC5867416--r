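## Secreted-protein biomarker nomination: intersect subgroup-discriminating
## DEGs with a secreted-protein annotation and report linear fold
## increases per subgroup, in the shape of a synovial-fluid candidate
## table.

#' Nominate secreted biomarker candidates from a subgroup contrast
#'
#' Filters the DEGs of the A-versus-B contrast against a secreted-protein
#' gene list. Each row reports the subgroup with higher expression and the
#' linear fold increase `2^|log2FC|`; rows are sorted by fold increase
#' (descending) within group. Secreted genes absent from the DE universe
#' are counted in the `n_secreted_not_tested` attribute rather than
#' silently dropped.
#'
#' @param de_groupAB `de_result` for the subgroup contrast (reference
#'   group first in its `contrast` attribute; positive fold change means
#'   higher in the second group).
#' @param secreted character vector of secreted-protein gene identifiers.
#' @param descriptions optional named character vector mapping gene to
#'   protein description.
#' @return Data.frame of class `biomarker_table` with columns gene,
#'   protein, group, fold_increase.
#' @export
secreted_biomarkers <- function(de_groupAB, secreted,
                                descriptions = NULL) {
  contrast <- attr(de_groupAB, "contrast") %||% c("A", "B")
  secreted <- unique(secreted)
  hits <- de_groupAB[de_groupAB$is_deg & de_groupAB$gene %in% secreted, ,
                     drop = FALSE]
  group <- ifelse(hits$log2FC > 0, contrast[2L], contrast[1L])
  protein <- if (is.null(descriptions)) rep(NA_character_, nrow(hits)) else
    as.character(descriptions[hits$gene])
  out <- data.frame(
    gene = hits$gene,
    protein = protein,
    group = group,
    fold_increase = 2^abs(hits$log2FC),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- out[order(out$group, -out$fold_increase), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_secreted_not_tested") <-
    length(setdiff(secreted, de_groupAB$gene))
  class(out) <- c("biomarker_table", class(out))
  out
}

#' Write a biomarker table to TSV
#'
#' Header `gene, protein, group, fold_increase`; an empty table produces a
#' header-only file. The file re-reads to an equal table.
#'
#' @param table a `biomarker_table`.
#' @param path output path.
#' @export
write_biomarker_report <- function(table, path) {
  write_tsv(as.data.frame(table)[, c("gene", "protein", "group",
                                     "fold_increase")], path)
}

#' Read a biomarker table written by [write_biomarker_report()]
#' @param path file path.
#' @return A `biomarker_table` data.frame.
#' @export
read_biomarker_report <- function(path) {
  df <- read_tsv(path, colClasses = c(gene = "character",
                                      protein = "character",
                                      group = "character",
                                      fold_increase = "numeric"))
  class(df) <- c("biomarker_table", class(df))
  df
}
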