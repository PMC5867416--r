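## Patient stratification by graph-regularised non-negative matrix
## factorisation (multiplicative updates with a graph-Laplacian penalty on
## the gene-factor matrix), aggregated over repeated seeded runs into a
## consensus co-clustering matrix. The number of clusters is chosen by mean
## silhouette of the average-linkage cut of 1 - co-clustering, and patients
## whose silhouette falls below a threshold are left unassigned.

#' Build the non-negative clustering matrix from an expression matrix
#'
#' Selects the most variable genes across the given samples and shifts each
#' gene to a non-negative range (per-gene minimum subtracted), the input
#' expected by [nmf_fit()].
#'
#' @param expr log2 expression matrix (genes x samples).
#' @param top_n number of top-variance genes to keep.
#' @return Non-negative numeric matrix (selected genes x samples).
#' @export
clustering_matrix <- function(expr, top_n = 2000) {
  expr <- as.matrix(expr)
  v <- apply(expr, 1L, var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(top_n, nrow(expr)))]
  x <- expr[sort(keep), , drop = FALSE]
  x - apply(x, 1L, min)
}

## Adjacency and degree aligned to a gene vector. With normalise = TRUE the
## adjacency is D^{-1/2} A D^{-1/2} and the degree term becomes the identity
## on genes present in the network (degree-normalised Laplacian penalty).
network_matrices <- function(network, genes, normalise = TRUE) {
  common <- intersect(genes, igraph::V(network)$name)
  A <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(length(genes), length(genes)),
                            dimnames = list(genes, genes))
  if (length(common) >= 2L) {
    sub <- igraph::induced_subgraph(network,
                                    igraph::V(network)$name %in% common)
    el <- igraph::as_data_frame(sub, what = "edges")
    if (nrow(el)) {
      w <- el$weight %||% rep(1, nrow(el))
      i <- match(el$from, genes); j <- match(el$to, genes)
      A <- A + Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                                    dims = dim(A), dimnames = dimnames(A))
    }
  }
  deg <- Matrix::rowSums(A)
  if (normalise) {
    pos <- deg > 0
    s <- numeric(length(deg)); s[pos] <- 1 / sqrt(deg[pos])
    A <- Matrix::Diagonal(x = s) %*% A %*% Matrix::Diagonal(x = s)
    dimnames(A) <- list(genes, genes)
    deg <- as.numeric(pos)
  }
  list(A = A, deg = deg)
}

#' Graph-regularised non-negative matrix factorisation
#'
#' Minimises `||X - WH||_F^2 + lambda * tr(W' L W)` by multiplicative
#' updates, where `L = D - A` is the (optionally degree-normalised)
#' Laplacian of the gene network restricted to the rows of `X`. With
#' `lambda = 0` or no network the updates reduce exactly to standard
#' Lee-Seung NMF. The objective trace is non-increasing.
#'
#' @param X non-negative gene x sample matrix.
#' @param k factorisation rank (number of clusters), `k < min(dim(X))`.
#' @param lambda non-negative network regularisation weight.
#' @param network optional [igraph::graph] over gene identifiers.
#' @param max_iter maximum number of update sweeps.
#' @param tol stop when the relative objective decrease falls below `tol`.
#' @param seed RNG seed for the random initialisation (ignored when `init`
#'   is supplied).
#' @param init optional list with matrices `W` (genes x k) and `H`
#'   (k x samples) used as the starting point.
#' @param normalise_laplacian use the degree-normalised Laplacian.
#' @return An object of class `nmf_fit`: list with `W`, `H`, `k`, `lambda`,
#'   `objective_trace`, `iterations`, `converged`.
#' @export
nmf_fit <- function(X, k, lambda = 0, network = NULL, max_iter = 200,
                    tol = 1e-5, seed = NULL, init = NULL,
                    normalise_laplacian = TRUE) {
  X <- as.matrix(X)
  if (any(X < 0)) abort("X must be non-negative")
  if (k >= min(dim(X))) abort("k must be smaller than both dimensions of X")
  if (k < 2L) abort("k must be at least 2")
  if (lambda < 0) abort("lambda must be non-negative")
  n_g <- nrow(X); n_s <- ncol(X)
  use_net <- lambda > 0 && !is.null(network)
  if (use_net) {
    nm <- network_matrices(network, rownames(X) %||% as.character(seq_len(n_g)),
                           normalise = normalise_laplacian)
    A <- nm$A; deg <- nm$deg
  }

  if (is.null(init)) {
    scale0 <- sqrt(mean(X) / k)
    init <- with_seed(seed, list(
      W = matrix(runif(n_g * k), n_g, k) * scale0,
      H = matrix(runif(k * n_s), k, n_s) * scale0
    ))
  }
  W <- init$W; H <- init$H
  stopifnot(nrow(W) == n_g, ncol(W) == k, nrow(H) == k, ncol(H) == n_s)

  eps <- 1e-12
  x_sq <- sum(X^2)
  objective <- function(WtX, WtW, HHt) {
    fit <- x_sq - 2 * sum(WtX * H) + sum(WtW * HHt)
    pen <- 0
    if (use_net) {
      AW <- as.matrix(A %*% W)
      pen <- lambda * (sum(W^2 * deg) - sum(W * AW))
    }
    fit + pen
  }

  trace <- numeric(max_iter + 1L)
  WtX <- crossprod(W, X); WtW <- crossprod(W); HHt <- tcrossprod(H)
  trace[1L] <- objective(WtX, WtW, HHt)
  it <- 0L; converged <- FALSE
  for (it in seq_len(max_iter)) {
    ## W update
    XHt <- X %*% t(H)
    num_W <- XHt
    den_W <- W %*% HHt
    if (use_net) {
      num_W <- num_W + lambda * as.matrix(A %*% W)
      den_W <- den_W + lambda * (W * deg)
    }
    W <- W * num_W / (den_W + eps)
    ## H update
    WtX <- crossprod(W, X)
    WtW <- crossprod(W)
    H <- H * WtX / (WtW %*% H + eps)
    HHt <- tcrossprod(H)
    trace[it + 1L] <- objective(WtX, WtW, HHt)
    rel <- (trace[it] - trace[it + 1L]) / max(trace[it], eps)
    if (is.finite(rel) && abs(rel) < tol) { converged <- TRUE; break }
  }
  structure(list(W = W, H = H, k = k, lambda = lambda,
                 objective_trace = trace[seq_len(it + 1L)],
                 iterations = it, converged = converged),
            class = "nmf_fit")
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat("NMF fit: rank", x$k, " lambda", x$lambda, " iterations", x$iterations,
      " objective", signif(tail(x$objective_trace, 1L), 6), "\n")
  invisible(x)
}

## hard labels from an NMF fit: argmax over the k rows of H per sample
## (ties broken toward the lowest cluster index)
nmf_labels <- function(fit) apply(fit$H, 2L, which.max)

#' Consensus co-clustering over repeated NMF runs
#'
#' Runs the factorisation `n_runs` times from random initialisations,
#' optionally on random sample subsets, labels each sample by the dominant
#' factor, and records for every sample pair the fraction of co-sampled
#' runs in which they received the same label.
#'
#' @param X non-negative gene x sample matrix (see [clustering_matrix()]).
#' @param k number of clusters per run.
#' @param n_runs number of runs (study default 500).
#' @param lambda,network,normalise_laplacian regularisation, see [nmf_fit()].
#' @param subsample_fraction fraction of samples drawn per run (1 = all).
#' @param seed root seed; each run derives its own stream.
#' @param max_iter,tol per-run NMF settings (consensus runs use a looser
#'   tolerance than a single final fit).
#' @return Symmetric sample x sample matrix in \[0, 1\] with unit diagonal.
#' @export
consensus_cluster <- function(X, k, n_runs = 500, lambda = 1, network = NULL,
                              subsample_fraction = 0.8, seed = 1,
                              max_iter = 100, tol = 1e-4,
                              normalise_laplacian = TRUE) {
  if (n_runs < 1L) abort("n_runs must be at least 1")
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    abort("subsample_fraction must be in (0, 1]")
  }
  X <- as.matrix(X)
  n_s <- ncol(X)
  n_sub <- max(k + 1L, floor(subsample_fraction * n_s))
  co <- matrix(0, n_s, n_s)
  together <- matrix(0, n_s, n_s)
  set.seed(seed)
  run_seeds <- sample.int(2147483646L, n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(run_seeds[r])
    idx <- if (n_sub < n_s) sort(sample.int(n_s, n_sub)) else seq_len(n_s)
    fit <- nmf_fit(X[, idx, drop = FALSE], k = k, lambda = lambda,
                   network = network, max_iter = max_iter, tol = tol,
                   normalise_laplacian = normalise_laplacian)
    lab <- nmf_labels(fit)
    together[idx, idx] <- together[idx, idx] + 1
    same <- outer(lab, lab, "==")
    co[idx, idx] <- co[idx, idx] + same
  }
  never <- together == 0
  diag(never) <- FALSE
  if (any(never)) {
    abort("some sample pairs were never co-sampled; increase ",
          "subsample_fraction or n_runs")
  }
  cc <- co / together
  diag(cc) <- 1
  dimnames(cc) <- list(colnames(X), colnames(X))
  cc
}

#' Per-sample silhouette widths
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a` the mean dissimilarity
#' to the sample's own cluster (excluding itself) and `b` the smallest mean
#' dissimilarity to any other cluster. Samples in singleton clusters get 0.
#'
#' @param d symmetric sample x sample dissimilarity matrix, zero diagonal.
#' @param labels cluster label per sample (at least two clusters).
#' @return Numeric vector of silhouette widths in \[-1, 1\].
#' @export
silhouette_widths <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (length(labels) != n) abort("one label per sample required")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    abort("dissimilarity matrix must be symmetric")
  }
  labels <- as.character(labels)
  cl <- unique(labels)
  if (length(cl) < 2L) abort("silhouette needs at least two clusters")
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(cl, labels[i]), function(cc) {
      mean(d[i, labels == cc])
    }, 0))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

## average-linkage cut of a consensus matrix into k clusters
cut_consensus <- function(coclustering, k) {
  d <- 1 - coclustering
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = "average")
  cutree(hc, k = k)
}

#' Assemble a consensus result from a pre-computed co-clustering matrix
#'
#' Cuts the matrix into `k` clusters by average linkage on
#' `1 - coclustering` and attaches per-sample silhouettes. Useful when the
#' ensemble was computed elsewhere (or constructed for testing).
#'
#' @param coclustering symmetric sample x sample co-occurrence matrix in
#'   \[0, 1\] with unit diagonal.
#' @param k number of clusters.
#' @param n_runs number of ensemble runs the matrix summarises.
#' @return An object of class `consensus_result`.
#' @export
consensus_from_matrix <- function(coclustering, k, n_runs = NA_integer_) {
  coclustering <- as.matrix(coclustering)
  if (any(coclustering < 0 | coclustering > 1)) {
    abort("co-clustering entries must lie in [0, 1]")
  }
  if (any(abs(diag(coclustering) - 1) > 1e-8)) {
    abort("co-clustering diagonal must be 1")
  }
  labels <- cut_consensus(coclustering, k)
  sil <- silhouette_widths(1 - coclustering, labels)
  samples <- colnames(coclustering) %||% paste0("s", seq_len(ncol(coclustering)))
  structure(list(
    coclustering = coclustering, n_runs = n_runs,
    labels = setNames(labels, samples),
    per_sample_silhouette = setNames(sil, samples),
    per_k_mean_silhouette = setNames(mean(sil), as.character(k)),
    chosen_k = k, samples = samples
  ), class = "consensus_result")
}

#' Select the number of clusters by consensus silhouette
#'
#' For each candidate `k`, builds the consensus co-clustering matrix, cuts
#' it by average linkage and scores the cut by mean silhouette on
#' `1 - coclustering`; the `k` with the highest mean silhouette wins, ties
#' broken toward smaller `k`.
#'
#' @param X non-negative clustering matrix (genes x samples).
#' @param k_range candidate cluster numbers (subset of 2..n_samples-1).
#' @param n_runs,lambda,network,subsample_fraction,seed,max_iter,tol,normalise_laplacian
#'   consensus settings, see [consensus_cluster()].
#' @return An object of class `consensus_result` holding the consensus
#'   matrix at the chosen `k`, the labels and silhouettes of its cut, and
#'   the per-k mean silhouette table.
#' @export
select_k <- function(X, k_range = 2:5, n_runs = 500, lambda = 1,
                     network = NULL, subsample_fraction = 0.8, seed = 1,
                     max_iter = 100, tol = 1e-4, normalise_laplacian = TRUE) {
  if (length(k_range) == 0L) abort("k_range must not be empty")
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L) || any(k_range > ncol(X) - 1L)) {
    abort("k_range must lie within 2..(n_samples - 1)")
  }
  mean_sil <- setNames(numeric(length(k_range)), as.character(k_range))
  results <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    cc <- consensus_cluster(X, k = k, n_runs = n_runs, lambda = lambda,
                            network = network,
                            subsample_fraction = subsample_fraction,
                            seed = stage_seed(seed, "stratify") + k,
                            max_iter = max_iter, tol = tol,
                            normalise_laplacian = normalise_laplacian)
    labels <- cut_consensus(cc, k)
    sil <- silhouette_widths(1 - cc, labels)
    mean_sil[i] <- mean(sil)
    results[[i]] <- list(coclustering = cc, labels = labels, sil = sil)
  }
  best <- which.max(mean_sil)      # ties resolve toward smaller k
  chosen <- results[[best]]
  samples <- colnames(X) %||% paste0("s", seq_len(ncol(X)))
  structure(list(
    coclustering = chosen$coclustering, n_runs = n_runs,
    labels = setNames(chosen$labels, samples),
    per_sample_silhouette = setNames(chosen$sil, samples),
    per_k_mean_silhouette = mean_sil,
    chosen_k = k_range[best], samples = samples
  ), class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus clustering of", length(x$samples), "samples over",
      x$n_runs, "runs\n")
  cat("  mean silhouette by k:",
      paste(names(x$per_k_mean_silhouette),
            signif(x$per_k_mean_silhouette, 3), sep = "=", collapse = "  "),
      "\n  chosen k:", x$chosen_k, "\n")
  invisible(x)
}

#' Final subgroup assignment with exclusion of poorly fitting samples
#'
#' Samples whose silhouette falls below `min_silhouette` are labelled
#' `"unassigned"` and flagged as excluded; the default threshold 0 is the
#' canonical "closer to another cluster" boundary.
#'
#' @param consensus a `consensus_result`.
#' @param min_silhouette exclusion threshold in \[-1, 1\].
#' @return A data.frame (sample, cluster, silhouette, excluded) with a
#'   `summary` attribute reporting group sizes and fractions.
#' @export
assign_with_exclusion <- function(consensus, min_silhouette = 0) {
  stopifnot(inherits(consensus, "consensus_result"))
  if (min_silhouette < -1 || min_silhouette > 1) {
    abort("min_silhouette must lie in [-1, 1]")
  }
  sil <- consensus$per_sample_silhouette
  cluster <- as.character(consensus$labels)
  excluded <- sil < min_silhouette
  cluster[excluded] <- "unassigned"
  out <- data.frame(sample = consensus$samples, cluster = cluster,
                    silhouette = sil, excluded = excluded,
                    row.names = NULL, stringsAsFactors = FALSE)
  sizes <- table(cluster)
  attr(out, "summary") <- data.frame(
    cluster = names(sizes), n = as.integer(sizes),
    fraction = as.numeric(sizes) / length(cluster),
    stringsAsFactors = FALSE
  )
  out
}

#' Test subgroup labels against clinical covariates
#'
#' Categorical covariates are tested by Fisher's exact test on the
#' contingency table with the subgroup labels, continuous covariates by a
#' Wilcoxon rank-sum test; p values are BH-adjusted across covariates.
#' Constant covariates are reported with p = 1 and a note. This is a
#' report, not a filter.
#'
#' @param labels assignment data.frame from [assign_with_exclusion()] (or a
#'   vector of labels); unassigned samples are dropped.
#' @param metadata per-sample metadata with a `sample` column.
#' @param covariates names of metadata columns to test.
#' @return Data.frame (covariate, type, p, padj, note).
#' @export
covariate_association <- function(labels, metadata, covariates) {
  if (is.data.frame(labels)) {
    lab <- setNames(labels$cluster, labels$sample)
  } else {
    lab <- labels
  }
  lab <- lab[lab != "unassigned" & !is.na(lab)]
  if (length(unique(lab)) != 2L) abort("need exactly two assigned groups")
  missing <- setdiff(covariates, names(metadata))
  if (length(missing)) {
    abort("covariate(s) absent from metadata: ", paste(missing, collapse = ", "))
  }
  md <- metadata[match(names(lab), metadata$sample), , drop = FALSE]
  res <- lapply(covariates, function(cv) {
    x <- md[[cv]]
    note <- ""
    if (length(unique(x[!is.na(x)])) < 2L) {
      return(data.frame(covariate = cv, type = "degenerate", p = 1,
                        note = "constant covariate", stringsAsFactors = FALSE))
    }
    if (is.numeric(x)) {
      p <- wilcox.test(x ~ factor(lab), exact = FALSE)$p.value
      type <- "continuous"
    } else {
      p <- fisher.test(table(x, lab))$p.value
      type <- "categorical"
    }
    data.frame(covariate = cv, type = type, p = p, note = note,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- bh_adjust(out$p)
  out[, c("covariate", "type", "p", "padj", "note")]
}
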