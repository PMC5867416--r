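## Count preprocessing and differential expression. The DE stage is a
## deliberately simplified negative-binomial Wald test: median-of-ratios
## size factors, method-of-moments gene dispersion with shrinkage toward a
## fitted mean-dispersion trend, and a normal reference for the Wald
## statistic. The contract is the thresholded DEG call (|FC| >= 1.5 at
## BH FDR <= 10%), validated by simulation, not bit-compatibility with any
## particular reference implementation.

#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors: the median across genes (restricted to
#' genes with a positive geometric mean) of the ratio of the gene's count to
#' its geometric mean over samples.
#'
#' @param counts non-negative integer gene x sample matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("counts must be non-negative")
  all_zero <- colSums(counts) == 0
  if (any(all_zero)) {
    abort("sample(s) with all-zero counts: ",
          paste(colnames(counts)[all_zero], collapse = ", "))
  }
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)          # genes with all counts > 0
  if (!any(use)) abort("no gene has a positive geometric mean; cannot normalise")
  lc <- log(counts[use, , drop = FALSE]) - log_geo[use]
  sf <- exp(apply(lc, 2L, median))
  if (any(!is.finite(sf) | sf <= 0)) abort("degenerate size factors")
  sf
}

#' Normalise counts to a log2 expression matrix
#'
#' Divides each sample by its size factor, adds a pseudocount and takes
#' log2. Genes with fewer than `min_total` total raw counts are removed
#' first; the filter and pseudocount are recorded in the `provenance`
#' attribute.
#'
#' @param counts gene x sample count matrix.
#' @param factors size factors; computed with [size_factors()] when `NULL`.
#' @param pseudocount positive value added before the log.
#' @param min_total low-count filter: minimum total raw counts per gene.
#' @return A numeric gene x sample matrix on the log2 scale with a
#'   `provenance` attribute.
#' @export
normalize_log <- function(counts, factors = NULL, pseudocount = 1,
                          min_total = 10) {
  if (pseudocount <= 0) abort("pseudocount must be positive")
  counts <- as.matrix(counts)
  keep <- rowSums(counts) >= min_total
  counts <- counts[keep, , drop = FALSE]
  factors <- factors %||% size_factors(counts)
  expr <- log2(sweep(counts, 2L, factors, "/") + pseudocount)
  attr(expr, "provenance") <- list(
    normalisation = "median-of-ratios size factors",
    pseudocount = pseudocount,
    low_count_filter = min_total,
    genes_removed = sum(!keep)
  )
  expr
}

#' Location-only batch correction
#'
#' Per gene and batch, subtracts the batch mean and adds back the grand
#' mean. This removes the additive (log-scale) shifts the simulator plants;
#' no scale adjustment is performed.
#'
#' @param expr log2 expression matrix (genes x samples).
#' @param batch batch label per sample.
#' @return Corrected matrix with updated `provenance`.
#' @export
batch_correct <- function(expr, batch) {
  if (length(batch) != ncol(expr)) abort("one batch label per sample required")
  batch <- as.factor(batch)
  prov <- attr(expr, "provenance")
  if (nlevels(batch) == 1L) return(expr)
  sizes <- table(batch)
  if (any(sizes < 2L)) {
    abort("singleton batch(es): ",
          paste(names(sizes)[sizes < 2L], collapse = ", "),
          "; cannot estimate a batch mean safely")
  }
  grand <- rowMeans(expr)
  out <- expr
  for (b in levels(batch)) {
    idx <- which(batch == b)
    out[, idx] <- expr[, idx] - rowMeans(expr[, idx, drop = FALSE]) + grand
  }
  attr(out, "provenance") <- c(prov, list(batch_correction = "location-only per gene"))
  out
}

#' Principal component embedding of samples
#'
#' SVD of the gene-centred expression matrix; samples are projected onto
#' the leading components.
#'
#' @param expr log2 expression matrix (genes x samples).
#' @param n_components number of components to return.
#' @return List with `coords` (sample x component matrix) and
#'   `var_explained` (non-increasing fractions summing to at most 1).
#' @export
pca_embed <- function(expr, n_components = 2) {
  x <- t(as.matrix(expr))
  if (n_components > min(dim(x))) {
    abort("n_components exceeds min(genes, samples)")
  }
  total_var <- sum(apply(x, 2L, var))
  if (!is.finite(total_var) || total_var == 0) {
    abort("constant expression matrix: no variance to decompose")
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = pc$x[, seq_len(n_components), drop = FALSE],
       var_explained = frac[seq_len(min(n_components, length(frac)))])
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; output order matches input
#' order and values are clipped to 1.
#'
#' @param p numeric p values in \[0, 1\].
#' @return Adjusted p values.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Negative-binomial Wald differential expression
#'
#' For each gene, estimates per-condition means on the common (size-factor
#' normalised) scale, a method-of-moments dispersion pooled within
#' conditions and shrunk toward a lowess mean-dispersion trend, and tests
#' the log2 fold change with a Wald statistic against a normal reference.
#' P values are BH-adjusted and the DEG flag applies the fold-change and
#' FDR thresholds jointly (boundary inclusive).
#'
#' @param counts gene x sample count matrix.
#' @param condition two-level factor (or coercible) per sample.
#' @param reference reference level; defaults to the first factor level.
#'   Positive `log2FC` means higher expression in the non-reference level.
#' @param fc_min minimum absolute linear fold change for a DEG (default 1.5).
#' @param fdr_max maximum BH-adjusted p for a DEG (default 0.10).
#' @param factors optional externally supplied size factors.
#' @param dispersion_shrinkage weight in \[0, 1\] pulling gene dispersions
#'   toward the fitted trend (on the log scale).
#' @return A data.frame of class `de_result` with columns gene, baseMean,
#'   log2FC, lfcSE, stat, pvalue, padj, is_deg. Genes with zero counts in
#'   every sample are excluded and listed in the `excluded_genes` attribute;
#'   the contrast levels are stored in the `contrast` attribute.
#' @export
de_test <- function(counts, condition, reference = NULL, fc_min = 1.5,
                    fdr_max = 0.10, factors = NULL,
                    dispersion_shrinkage = 0.3) {
  counts <- as.matrix(counts)
  condition <- as.factor(as.character(condition))
  if (nlevels(condition) != 2L) abort("condition must have exactly two levels")
  if (length(condition) != ncol(counts)) abort("one condition label per sample")
  if (!is.null(reference)) condition <- relevel(condition, ref = reference)
  lv <- levels(condition)
  if (min(table(condition)) < 2L) abort("each condition needs >= 2 samples")
  if (fc_min < 1) abort("fc_min must be >= 1")
  if (fdr_max <= 0 || fdr_max > 1) abort("fdr_max must be in (0, 1]")

  excluded <- rownames(counts)[rowSums(counts) == 0]
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  sf <- factors %||% size_factors(counts)
  z <- sweep(counts, 2L, sf, "/")         # normalised counts
  idx1 <- which(condition == lv[1L])
  idx2 <- which(condition == lv[2L])
  n1 <- length(idx1); n2 <- length(idx2)
  inv_sf_mean <- mean(1 / sf)

  q1 <- rowMeans(z[, idx1, drop = FALSE])
  q2 <- rowMeans(z[, idx2, drop = FALSE])
  base_mean <- rowMeans(z)

  ## pooled within-condition moment dispersion:
  ## Var(K_j/s_j) ~ q * mean(1/s) + alpha * q^2
  v1 <- apply(z[, idx1, drop = FALSE], 1L, var)
  v2 <- apply(z[, idx2, drop = FALSE], 1L, var)
  v_pool <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  q_pool <- (n1 * q1 + n2 * q2) / (n1 + n2)
  disp_raw <- pmax((v_pool - q_pool * inv_sf_mean) / q_pool^2, 1e-8)

  disp <- disp_raw
  if (dispersion_shrinkage > 0 && nrow(counts) >= 10L) {
    ord <- order(q_pool)
    tr <- lowess(log(q_pool[ord]), log(disp_raw[ord]), f = 0.5)
    trend <- exp(approx(tr$x, tr$y, xout = log(q_pool), rule = 2)$y)
    disp <- exp((1 - dispersion_shrinkage) * log(disp_raw) +
                  dispersion_shrinkage * log(trend))
  }

  ## guard empty groups: smallest observable positive normalised mean
  q_floor <- 0.5 * inv_sf_mean
  q1g <- pmax(q1, q_floor / n1)
  q2g <- pmax(q2, q_floor / n2)
  lfc <- log2(q2g / q1g)

  ## delta-method variance of log2 of each group mean
  var_log2 <- function(q, n) (inv_sf_mean / (n * q) + disp / n) / log(2)^2
  se <- sqrt(var_log2(q1g, n1) + var_log2(q2g, n2))
  stat <- lfc / se
  pval <- 2 * pnorm(-abs(stat))
  padj <- bh_adjust(pval)
  is_deg <- abs(lfc) >= log2(fc_min) & padj <= fdr_max

  out <- data.frame(
    gene = rownames(counts), baseMean = base_mean, log2FC = lfc,
    lfcSE = se, stat = stat, pvalue = pval, padj = padj, is_deg = is_deg,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "contrast") <- lv          # reference first
  attr(out, "excluded_genes") <- excluded
  attr(out, "thresholds") <- c(fc_min = fc_min, fdr_max = fdr_max)
  class(out) <- c("de_result", class(out))
  out
}

#' Extract the DEG identifiers from a DE result
#' @param de a `de_result`.
#' @return Character vector of genes flagged as differentially expressed.
#' @export
deg_genes <- function(de) de$gene[de$is_deg]

#' Compare DEG sets across contrasts
#'
#' Partitions the union of DEG identifiers from a combined contrast and two
#' subgroup contrasts by membership pattern, reporting in particular the
#' genes distinctive to each subgroup (detected in that subgroup's contrast
#' but not the other's) and those missed by the combined analysis.
#'
#' @param de_all,de_groupA,de_groupB `de_result` objects on the same gene
#'   universe (combined OA vs control, A vs control, B vs control).
#' @return A list with a `pattern` data.frame (one row per membership
#'   pattern, counts summing to the union size) and a `summary` vector
#'   (n_all, n_A, n_B, distinctive_A, distinctive_B, shared_AB,
#'   additional_vs_all).
#' @export
compare_deg_sets <- function(de_all, de_groupA, de_groupB) {
  uni <- sort(de_all$gene)
  if (!identical(sort(de_groupA$gene), uni) ||
      !identical(sort(de_groupB$gene), uni)) {
    abort("DE results are not on the same gene universe")
  }
  sets <- list(all = deg_genes(de_all), A = deg_genes(de_groupA),
               B = deg_genes(de_groupB))
  union_genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) union_genes %in% s,
                   logical(length(union_genes)))
  if (length(union_genes) == 1L) member <- matrix(member, nrow = 1L,
                                                  dimnames = list(NULL, names(sets)))
  pat <- apply(member, 1L, function(r) paste(ifelse(r, names(sets), ""),
                                             collapse = ""))
  pattern <- as.data.frame(table(pattern = pat), stringsAsFactors = FALSE)
  names(pattern)[2L] <- "count"
  summary <- c(
    n_all = length(sets$all), n_A = length(sets$A), n_B = length(sets$B),
    distinctive_A = sum(member[, "A"] & !member[, "B"]),
    distinctive_B = sum(member[, "B"] & !member[, "A"]),
    shared_AB = sum(member[, "A"] & member[, "B"]),
    additional_vs_all = sum((member[, "A"] | member[, "B"]) & !member[, "all"]),
    union = length(union_genes)
  )
  list(pattern = pattern, summary = summary)
}
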