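## Marker-panel derivation by nearest shrunken centroids (NSC) and a
## cross-validated linear SVM on the selected panel. The NSC statistics
## follow the canonical formulation: standardised class-centroid distances
## d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s0)) with pooled within-class
## s_i, s0 the median of the s_i, and m_k = sqrt(1/n_k - 1/n); shrinkage is
## soft thresholding of d_ik by delta.

#' Nearest-shrunken-centroid statistics
#'
#' @param expr log2 expression matrix (genes x samples).
#' @param labels two-class label per sample, each class with >= 2 samples.
#' @return Object of class `nsc_stats`: per-gene per-class standardised
#'   centroid distances `d`, class centroids, overall centroid, pooled
#'   within-class standard deviations `s`, fudge constant `s0`, class sizes
#'   and priors.
#' @export
nsc_statistics <- function(expr, labels) {
  expr <- as.matrix(expr)
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) != 2L) abort("exactly two classes required")
  if (length(labels) != ncol(expr)) abort("one label per sample required")
  n_k <- table(labels)
  if (any(n_k < 2L)) abort("each class needs at least 2 samples")
  n <- ncol(expr)
  cls <- levels(labels)

  centroids <- vapply(cls, function(cc) {
    rowMeans(expr[, labels == cc, drop = FALSE])
  }, numeric(nrow(expr)))
  overall <- rowMeans(expr)

  ## pooled within-class variance with n - K degrees of freedom
  ss <- rowSums(vapply(cls, function(cc) {
    x <- expr[, labels == cc, drop = FALSE]
    rowSums((x - centroids[, cc])^2)
  }, numeric(nrow(expr))))
  s <- sqrt(ss / (n - length(cls)))
  s0 <- median(s)
  m_k <- sqrt(1 / as.numeric(n_k) - 1 / n)
  names(m_k) <- cls

  d <- vapply(cls, function(cc) {
    (centroids[, cc] - overall) / (m_k[cc] * (s + s0))
  }, numeric(nrow(expr)))
  rownames(d) <- rownames(expr)

  structure(list(d = d, centroids = centroids, overall = overall,
                 s = s, s0 = s0, m_k = m_k,
                 n_k = setNames(as.numeric(n_k), cls),
                 prior = setNames(as.numeric(n_k) / n, cls),
                 classes = cls),
            class = "nsc_stats")
}

#' Shrink centroid distances and select the marker panel
#'
#' Soft-thresholds each standardised distance,
#' `d'_ik = sign(d_ik) * max(|d_ik| - delta, 0)`; the panel is every gene
#' with a nonzero shrunken distance in at least one class, ordered by the
#' largest absolute shrunken distance. Panels shrink monotonically as
#' `delta` grows; an empty panel is a valid result.
#'
#' @param stats an `nsc_stats` object.
#' @param delta non-negative shrinkage threshold.
#' @return Object of class `classifier_panel` with the ordered panel genes,
#'   `delta`, the shrunken distance matrix and everything needed to
#'   classify new samples by shrunken centroids.
#' @export
shrink_and_select <- function(stats, delta) {
  stopifnot(inherits(stats, "nsc_stats"))
  if (delta < 0) abort("delta must be non-negative")
  d_shrunk <- sign(stats$d) * pmax(abs(stats$d) - delta, 0)
  keep <- rowSums(abs(d_shrunk) > 0) > 0
  genes <- rownames(stats$d)[keep]
  ord <- order(apply(abs(d_shrunk[keep, , drop = FALSE]), 1L, max),
               decreasing = TRUE)
  genes <- genes[ord]
  structure(list(genes = genes, delta = delta,
                 d_shrunk = d_shrunk[genes, , drop = FALSE],
                 stats = stats),
            class = "classifier_panel")
}

#' @export
print.classifier_panel <- function(x, ...) {
  cat("NSC panel:", length(x$genes), "genes at delta =", signif(x$delta, 4), "\n")
  if (length(x$genes)) cat("  top genes:",
                           paste(head(x$genes, 10L), collapse = ", "), "\n")
  invisible(x)
}

## shrunken-centroid discriminant classification of new samples
nsc_predict <- function(panel, newdata) {
  stats <- panel$stats
  if (length(panel$genes) == 0L) {
    ## empty panel: fall back to the prior
    win <- stats$classes[which.max(stats$prior)]
    return(rep(win, ncol(newdata)))
  }
  genes <- panel$genes
  shrunk_centroid <- vapply(stats$classes, function(cc) {
    stats$overall[genes] + stats$m_k[cc] * (stats$s[genes] + stats$s0) *
      panel$d_shrunk[genes, cc]
  }, numeric(length(genes)))
  if (!is.matrix(shrunk_centroid)) {   # single-gene panel: keep matrix shape
    shrunk_centroid <- matrix(shrunk_centroid, nrow = length(genes),
                              dimnames = list(genes, stats$classes))
  }
  x <- newdata[genes, , drop = FALSE]
  denom <- (stats$s[genes] + stats$s0)^2
  score <- vapply(stats$classes, function(cc) {
    colSums((x - shrunk_centroid[, cc])^2 / denom) - 2 * log(stats$prior[cc])
  }, numeric(ncol(newdata)))
  if (ncol(newdata) == 1L) score <- matrix(score, nrow = 1L,
                                           dimnames = list(NULL, stats$classes))
  stats$classes[apply(score, 1L, which.min)]
}

#' Choose the shrinkage threshold by cross-validation
#'
#' Stratified k-fold cross-validation of the NSC classifier over a grid of
#' thresholds; the chosen `delta` is the largest one achieving the minimum
#' CV misclassification rate (parsimony tie-break).
#'
#' @param expr log2 expression matrix (genes x samples).
#' @param labels two-class label per sample.
#' @param delta_grid candidate thresholds; defaults to 30 values spanning
#'   0 to the largest observed |d|.
#' @param folds number of folds.
#' @param seed RNG seed for the fold assignment.
#' @return List with `delta` and `cv_error_by_delta` (data.frame).
#' @export
choose_delta_cv <- function(expr, labels, delta_grid = NULL, folds = 5,
                            seed = 1) {
  if (folds < 2L) abort("folds must be at least 2")
  expr <- as.matrix(expr)
  labels <- as.factor(as.character(labels))
  if (!is.null(delta_grid) && length(delta_grid) == 0L) {
    abort("delta_grid must not be empty")
  }
  full_stats <- nsc_statistics(expr, labels)
  delta_grid <- delta_grid %||% seq(0, max(abs(full_stats$d)), length.out = 30)
  fold_id <- with_seed(seed, stratified_folds(labels, folds))
  errs <- matrix(NA_real_, length(delta_grid), folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    st <- nsc_statistics(expr[, tr, drop = FALSE], labels[tr])
    for (i in seq_along(delta_grid)) {
      panel <- shrink_and_select(st, delta_grid[i])
      pred <- nsc_predict(panel, expr[, !tr, drop = FALSE])
      errs[i, f] <- mean(pred != as.character(labels[!tr]))
    }
  }
  cv_err <- rowMeans(errs)
  best <- max(delta_grid[cv_err <= min(cv_err) + 1e-12])
  list(delta = best,
       cv_error_by_delta = data.frame(delta = delta_grid, cv_error = cv_err))
}

#' Select the smallest panel of at most a target size
#'
#' Searches the shrinkage threshold for the smallest `delta` whose panel
#' has at most `size` genes (the panel-size-to-delta map is a
#' non-increasing step function, so the search is exact).
#'
#' @param stats an `nsc_stats` object.
#' @param size maximum panel size (the study derived a 10-gene panel).
#' @return A `classifier_panel` with at most `size` genes.
#' @export
select_panel_size <- function(stats, size) {
  stopifnot(inherits(stats, "nsc_stats"), size >= 1L)
  dmax <- apply(abs(stats$d), 1L, max)
  v <- sort(dmax, decreasing = TRUE)
  if (length(v) <= size) return(shrink_and_select(stats, 0))
  ## any delta in [v[size+1], v[size]) yields exactly `size` genes
  ## (fewer under ties); midpoint keeps the selection stable
  delta <- (v[size] + v[size + 1L]) / 2
  if (v[size] == v[size + 1L]) delta <- v[size]   # ties: shrink below target
  shrink_and_select(stats, delta)
}

#' Train and cross-validate a linear SVM on a marker panel
#'
#' Fits a soft-margin linear SVM on the panel genes, with per-gene
#' standardisation computed from training folds only, and reports the
#' rank-based (Mann-Whitney) AUC of the pooled held-out decision scores.
#' The final model is refit on all samples.
#'
#' @param expr log2 expression matrix (genes x samples).
#' @param labels two-class label per sample.
#' @param panel a `classifier_panel` or a character vector of panel genes.
#' @param folds number of stratified CV folds (study default 5).
#' @param cost soft-margin cost (not tuned inside the reporting CV).
#' @param seed RNG seed for the fold assignment.
#' @return Object of class `panel_classifier` with the panel, per-gene
#'   standardisation constants, linear weights and bias, `cv_auc`,
#'   `cv_folds` and the pooled held-out scores.
#' @export
train_panel_classifier <- function(expr, labels, panel, folds = 5, cost = 1,
                                   seed = 1) {
  expr <- as.matrix(expr)
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) != 2L) abort("exactly two classes required")
  genes <- if (inherits(panel, "classifier_panel")) panel$genes else
    as.character(panel)
  if (length(genes) == 0L) abort("panel must be non-empty")
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) abort("panel gene(s) absent from expression matrix: ",
                             paste(missing, collapse = ", "))
  x <- t(expr[genes, , drop = FALSE])      # samples x genes
  pos_class <- levels(labels)[2L]

  fold_id <- with_seed(seed, stratified_folds(labels, folds))
  held_scores <- numeric(nrow(x))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    ctr <- colMeans(x[tr, , drop = FALSE])
    scl <- apply(x[tr, , drop = FALSE], 2L, sd)
    scl[scl == 0] <- 1
    xtr <- scale(x[tr, , drop = FALSE], ctr, scl)
    xte <- scale(x[!tr, , drop = FALSE], ctr, scl)
    fit <- e1071::svm(xtr, labels[tr], kernel = "linear", cost = cost,
                      scale = FALSE)
    sc_tr <- as.numeric(attr(
      predict(fit, xtr, decision.values = TRUE), "decision.values"))
    sc_te <- as.numeric(attr(
      predict(fit, xte, decision.values = TRUE), "decision.values"))
    ## orient scores so larger = positive class, using training data only
    if (rank_auc(sc_tr, labels[tr] == pos_class) < 0.5) sc_te <- -sc_te
    held_scores[!tr] <- sc_te
  }
  cv_auc <- rank_auc(held_scores, labels == pos_class)

  ## final model on all samples
  ctr <- colMeans(x); scl <- apply(x, 2L, sd); scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  fit <- e1071::svm(xs, labels, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  sc <- drop(xs %*% w) + b
  if (rank_auc(sc, labels == pos_class) < 0.5) { w <- -w; b <- -b }

  structure(list(
    panel = genes, classes = levels(labels), positive_class = pos_class,
    center = setNames(as.numeric(ctr), genes),
    scale = setNames(as.numeric(scl), genes),
    weights = setNames(as.numeric(w), genes), bias = b,
    cost = cost, cv_auc = cv_auc, cv_folds = folds,
    held_out_scores = setNames(held_scores, rownames(x))
  ), class = "panel_classifier")
}

#' @export
print.panel_classifier <- function(x, ...) {
  cat("Linear SVM on", length(x$panel), "panel genes;",
      x$cv_folds, "fold CV AUC =", round(x$cv_auc, 3), "\n")
  invisible(x)
}

#' Classify new samples with a trained panel classifier
#'
#' Applies the stored per-gene standardisation and linear decision
#' function; positive scores map to the positive class. New matrices are
#' accepted on any log2-like scale (e.g. RT-qPCR negative delta-Ct values),
#' since standardisation absorbs the scale convention.
#'
#' @param model a `panel_classifier`.
#' @param new_expr gene x sample matrix containing all panel genes.
#' @return Data.frame (sample, group, score).
#' @export
classify_samples <- function(model, new_expr) {
  stopifnot(inherits(model, "panel_classifier"))
  new_expr <- as.matrix(new_expr)
  missing <- setdiff(model$panel, rownames(new_expr))
  if (length(missing)) {
    abort("panel gene(s) missing from input: ", paste(missing, collapse = ", "))
  }
  x <- t(new_expr[model$panel, , drop = FALSE])
  xs <- scale(x, model$center[model$panel], model$scale[model$panel])
  score <- drop(xs %*% model$weights[model$panel]) + model$bias
  neg_class <- setdiff(model$classes, model$positive_class)
  data.frame(
    sample = colnames(new_expr) %||% paste0("s", seq_len(ncol(new_expr))),
    group = ifelse(score > 0, model$positive_class, neg_class),
    score = as.numeric(score),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Serialise a panel classifier to JSON
#' @param model a `panel_classifier`.
#' @param path output path.
#' @export
write_classifier_json <- function(model, path) {
  jsonlite::write_json(
    list(panel = model$panel, classes = model$classes,
         positive_class = model$positive_class,
         center = as.list(model$center), scale = as.list(model$scale),
         weights = as.list(model$weights), bias = model$bias,
         cost = model$cost, cv_auc = model$cv_auc, cv_folds = model$cv_folds),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a panel classifier written by [write_classifier_json()]
#' @param path file path.
#' @return A `panel_classifier`.
#' @export
read_classifier_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    panel = j$panel, classes = j$classes, positive_class = j$positive_class,
    center = unlist(j$center), scale = unlist(j$scale),
    weights = unlist(j$weights), bias = j$bias, cost = j$cost,
    cv_auc = j$cv_auc, cv_folds = j$cv_folds
  ), class = "panel_classifier")
}
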