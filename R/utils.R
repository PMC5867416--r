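## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible per-stage seed from a root seed
#'
#' All stochastic stages draw their seed from one root seed through named
#' substreams, so stages can be re-run independently yet reproducibly.
#'
#' @param root integer root seed.
#' @param stage character stage name.
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(root, stage) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(stage))
  streams <- c(
    simulate = 1L, network = 2L, de = 3L, stratify = 4L,
    classify = 5L, pathways = 6L, biomarkers = 7L, pipeline = 8L
  )
  if (!stage %in% names(streams)) stop("unknown stage: ", stage)
  idx <- streams[[stage]]
  as.integer((abs(as.numeric(root)) * 131 + idx * 7919) %% 2147483647)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same samples;
#' used to quantify recovery of planted subgroups.
#'
#' @param a,b label vectors of equal length.
#' @return Numeric scalar in \[-1, 1\]; 1 for identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

## stop() with call.=FALSE everywhere, for clean CLI errors
abort <- function(...) stop(..., call. = FALSE)

## evaluate expr under a local RNG state seeded with `seed` (NULL = leave RNG)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## rank-based (Mann-Whitney) AUC of scores for the positive class
rank_auc <- function(scores, is_positive) {
  stopifnot(length(scores) == length(is_positive))
  n_pos <- sum(is_positive)
  n_neg <- sum(!is_positive)
  if (n_pos == 0L || n_neg == 0L) abort("AUC needs both classes represented")
  r <- rank(scores)
  (sum(r[is_positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

## stratified fold assignment: returns integer fold id per sample
stratified_folds <- function(labels, folds) {
  labels <- as.factor(labels)
  fold_id <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < folds) {
      abort("class '", cl, "' has fewer samples (", length(idx),
            ") than folds (", folds, "); use fewer folds")
    }
    fold_id[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}
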