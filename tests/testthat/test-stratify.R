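## A small well-separated two-block matrix used throughout: gene block 1 is
## elevated in samples 1..8, gene block 2 in samples 9..16.
block_matrix <- function(n_genes = 60, n_per_group = 8, signal = 4,
                         noise = 0.3, seed = 11) {
  set.seed(seed)
  n_s <- 2L * n_per_group
  X <- matrix(abs(rnorm(n_genes * n_s, 1, noise)), n_genes, n_s)
  half <- n_genes %/% 2L
  X[seq_len(half), seq_len(n_per_group)] <- X[seq_len(half), seq_len(n_per_group)] + signal
  X[(half + 1L):n_genes, (n_per_group + 1L):n_s] <- X[(half + 1L):n_genes, (n_per_group + 1L):n_s] + signal
  dimnames(X) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("s%02d", seq_len(n_s)))
  X
}

test_that("clustering_matrix keeps the most variable genes, shifted non-negative", {
  set.seed(4)
  expr <- matrix(rnorm(40 * 10), 40, 10,
                 dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:10)))
  expr["g05", ] <- expr["g05", ] * 20   # by far the highest variance
  cm <- clustering_matrix(expr, top_n = 5)
  expect_equal(dim(cm), c(5L, 10L))
  expect_true("g05" %in% rownames(cm))
  expect_true(all(cm >= 0))
  expect_equal(unname(apply(cm, 1L, min)), rep(0, 5))
  ## top_n larger than the gene count keeps everything
  expect_equal(nrow(clustering_matrix(expr, top_n = 100)), 40L)
})

test_that("unregularised nmf_fit reproduces reference Lee-Seung updates", {
  X <- block_matrix()
  k <- 2L
  set.seed(42)
  init <- list(W = matrix(runif(nrow(X) * k), nrow(X), k),
               H = matrix(runif(k * ncol(X)), k, ncol(X)))
  n_iter <- 25L
  ## tol = 0 forces exactly max_iter sweeps
  fit <- nmf_fit(X, k, lambda = 0, init = init, max_iter = n_iter, tol = 0)
  ref <- reference_lee_seung(X, init$W, init$H, n_iter)
  expect_equal(fit$W, ref$W, tolerance = 1e-10)
  expect_equal(fit$H, ref$H, tolerance = 1e-10)
  expect_equal(fit$iterations, n_iter)

  ## lambda = 0 ignores a supplied network entirely
  net <- random_gene_network(rownames(X), p = 0.2, seed = 3)
  fit_net0 <- nmf_fit(X, k, lambda = 0, network = net, init = init,
                      max_iter = n_iter, tol = 0)
  expect_identical(fit_net0$W, fit$W)
  expect_identical(fit_net0$H, fit$H)
})

test_that("the NMF objective trace is non-increasing, with and without network", {
  X <- block_matrix(seed = 12)
  net <- random_gene_network(rownames(X), p = 0.15, seed = 5)
  for (lam in c(0, 1, 10)) {
    fit <- nmf_fit(X, 2, lambda = lam, network = net, seed = 6,
                   max_iter = 150, tol = 1e-9)
    expect_true(all(diff(fit$objective_trace) <= 1e-8 * fit$objective_trace[1]))
  }
})

test_that("the final NMF objective equals its definition computed from scratch", {
  X <- block_matrix(seed = 13)
  net <- random_gene_network(rownames(X), p = 0.15, seed = 7)
  fit <- nmf_fit(X, 2, lambda = 2, network = net, seed = 8, max_iter = 60,
                 tol = 0, normalise_laplacian = FALSE)
  ## unnormalised Laplacian from igraph, aligned to the rows of X
  A <- as.matrix(igraph::as_adjacency_matrix(net, attr = "weight"))
  A <- A[rownames(X), rownames(X)]
  L <- diag(rowSums(A)) - A
  obj <- sum((X - fit$W %*% fit$H)^2) +
    2 * sum(diag(t(fit$W) %*% L %*% fit$W))
  expect_equal(unname(tail(fit$objective_trace, 1)), obj, tolerance = 1e-8)
})

test_that("network regularisation smooths W over the graph", {
  X <- block_matrix(seed = 14)
  ## network whose edges connect only genes of the same planted block
  half <- nrow(X) %/% 2L
  truth <- list(de_genes_shared = numeric(0),
                de_genes_A = setNames(rep(1, half), rownames(X)[1:half]),
                de_genes_B = setNames(rep(1, half), rownames(X)[(half + 1):nrow(X)]),
                gene_ids = rownames(X))
  net <- simulate_network(truth, module_density = 0.4, background_degree = 0,
                          seed = 15)
  A <- as.matrix(igraph::as_adjacency_matrix(net, attr = "weight"))
  A <- A[rownames(X), rownames(X)]
  L <- diag(rowSums(A)) - A
  penalty <- function(fit) {
    W <- fit$W / sqrt(rowSums(fit$W^2) + 1e-12)   # scale-free comparison
    sum(diag(t(W) %*% L %*% W))
  }
  f0 <- nmf_fit(X, 2, lambda = 0, seed = 16, max_iter = 200, tol = 1e-8)
  f1 <- nmf_fit(X, 2, lambda = 20, network = net, seed = 16, max_iter = 200,
                tol = 1e-8, normalise_laplacian = FALSE)
  expect_lt(penalty(f1), penalty(f0))
})

test_that("nmf_fit validates its inputs", {
  X <- block_matrix()
  expect_error(nmf_fit(X - 10, 2), "non-negative")
  expect_error(nmf_fit(X, 1), "at least 2")
  expect_error(nmf_fit(X, ncol(X)), "smaller")
  expect_error(nmf_fit(X, 2, lambda = -1), "non-negative")
  ## identical seed gives identical fits
  f1 <- nmf_fit(X, 2, seed = 9, max_iter = 20, tol = 0)
  f2 <- nmf_fit(X, 2, seed = 9, max_iter = 20, tol = 0)
  expect_identical(f1$W, f2$W)
})

test_that("consensus matrices are valid co-occurrence summaries", {
  X <- block_matrix(seed = 17)
  cc <- consensus_cluster(X, k = 2, n_runs = 30, lambda = 0,
                          subsample_fraction = 0.8, seed = 20)
  expect_equal(cc, t(cc))
  expect_true(all(cc >= 0 & cc <= 1))
  expect_equal(unname(diag(cc)), rep(1, ncol(X)))
  expect_equal(colnames(cc), colnames(X))
  ## deterministic in the seed
  cc2 <- consensus_cluster(X, k = 2, n_runs = 30, lambda = 0,
                           subsample_fraction = 0.8, seed = 20)
  expect_identical(cc, cc2)
  ## clear two-block data: within-block co-clustering near 1, between near 0
  blocks <- rep(1:2, each = ncol(X) / 2)
  same <- outer(blocks, blocks, "==")
  expect_gt(mean(cc[same]), 0.95)
  expect_lt(mean(cc[!same]), 0.05)

  ## a single full-data run gives a 0/1 matrix
  cc1 <- consensus_cluster(X, k = 2, n_runs = 1, lambda = 0,
                           subsample_fraction = 1, seed = 21)
  expect_true(all(cc1 %in% c(0, 1)))

  ## pairs never drawn together must raise an error
  expect_error(consensus_cluster(X, k = 2, n_runs = 1, lambda = 0,
                                 subsample_fraction = 0.3, seed = 22),
               "never co-sampled")
  expect_error(consensus_cluster(X, k = 2, n_runs = 0), "at least 1")
})

test_that("silhouette widths agree with cluster::silhouette", {
  set.seed(23)
  pts <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 3), 10, 2),
               matrix(rnorm(20, -3), 10, 2))
  lab <- rep(1:3, each = 10)
  d <- as.matrix(dist(pts))
  ours <- silhouette_widths(d, lab)
  ref <- cluster::silhouette(lab, dist(pts))[, "sil_width"]
  expect_equal(ours, unname(ref), tolerance = 1e-12)

  ## hand-checked toy: 4 points on a line at 0, 1, 10, 11, clusters {1,2},{3,4}
  dd <- as.matrix(dist(c(0, 1, 10, 11)))
  s <- silhouette_widths(dd, c(1, 1, 2, 2))
  ## point 1: a = 1, b = mean(10, 11) = 10.5 -> s = 9.5 / 10.5
  expect_equal(s[1], 9.5 / 10.5)
  ## singleton cluster gets 0
  s2 <- silhouette_widths(dd, c(1, 2, 2, 2))
  expect_equal(s2[1], 0)
  expect_error(silhouette_widths(dd, c(1, 1, 1, 1)), "two clusters")
  expect_error(silhouette_widths(dd[1:3, ], c(1, 1, 2)))
})

test_that("select_k recovers the planted number of clusters and partition", {
  X <- block_matrix(n_genes = 80, n_per_group = 9, seed = 24)
  res <- select_k(X, k_range = 2:4, n_runs = 40, lambda = 0,
                  subsample_fraction = 0.8, seed = 25)
  expect_s3_class(res, "consensus_result")
  expect_equal(res$chosen_k, 2L)
  expect_equal(names(which.max(res$per_k_mean_silhouette)), "2")
  truth <- rep(1:2, each = 9)
  ari <- adjusted_rand_index(res$labels, truth)
  expect_equal(ari, 1)
  ## our ARI agrees with the mclust implementation
  expect_equal(ari, mclust::adjustedRandIndex(res$labels, truth))
  expect_error(select_k(X, k_range = integer(0)), "empty")
  expect_error(select_k(X, k_range = c(2, ncol(X))), "2..")
})

test_that("consensus_from_matrix validates and reproduces block structure", {
  ## ideal two-block consensus: labels follow the blocks, silhouettes = 1
  n <- 10L
  cc <- matrix(0, n, n, dimnames = list(paste0("s", 1:n), paste0("s", 1:n)))
  blocks <- rep(1:2, each = n / 2)
  cc[outer(blocks, blocks, "==")] <- 1
  res <- consensus_from_matrix(cc, k = 2, n_runs = 100)
  expect_equal(adjusted_rand_index(res$labels, blocks), 1)
  expect_equal(unname(res$per_sample_silhouette), rep(1, n))
  expect_equal(res$n_runs, 100)

  bad <- cc; bad[1, 2] <- 1.5; bad[2, 1] <- 1.5
  expect_error(consensus_from_matrix(bad, 2), "0, 1")
  bad2 <- cc; diag(bad2)[3] <- 0.4
  expect_error(consensus_from_matrix(bad2, 2), "diagonal")
})

test_that("assignment excludes samples below the silhouette threshold", {
  n <- 10L
  cc <- matrix(0, n, n, dimnames = list(paste0("s", 1:n), paste0("s", 1:n)))
  blocks <- rep(1:2, each = n / 2)
  cc[outer(blocks, blocks, "==")] <- 1
  ## blur one sample halfway between the blocks
  cc[1, ] <- cc[, 1] <- 0.5; cc[1, 1] <- 1
  res <- consensus_from_matrix(cc, k = 2)
  asg <- assign_with_exclusion(res, min_silhouette = 0)
  expect_s3_class(asg, "data.frame")
  expect_equal(asg$cluster == "unassigned", asg$excluded)
  ## clean samples all keep their block label
  expect_true(all(!asg$excluded[2:n]))
  smry <- attr(asg, "summary")
  expect_equal(sum(smry$n), n)
  expect_equal(sum(smry$fraction), 1)

  ## threshold 1 removes every sample with silhouette < 1
  asg1 <- assign_with_exclusion(res, min_silhouette = 1)
  expect_true(all(asg1$excluded[asg1$silhouette < 1]))
  ## thresholds outside [-1, 1] are rejected
  expect_error(assign_with_exclusion(res, min_silhouette = 1.01), "-1, 1")
  expect_error(assign_with_exclusion(res, min_silhouette = -2), "-1, 1")
})

test_that("covariate association flags informative covariates only", {
  set.seed(26)
  n <- 30L
  lab <- data.frame(sample = paste0("s", 1:n),
                    cluster = rep(c("A", "B"), each = n / 2),
                    silhouette = 1, excluded = FALSE,
                    stringsAsFactors = FALSE)
  md <- data.frame(
    sample = paste0("s", 1:n),
    linked = rep(c("x", "y"), each = n / 2),          # perfectly associated
    age = c(rnorm(n / 2, 50, 3), rnorm(n / 2, 70, 3)),# strongly shifted
    noise = sample(c("u", "v"), n, replace = TRUE),   # independent
    const = "same",                                   # degenerate
    stringsAsFactors = FALSE
  )
  res <- covariate_association(lab, md, c("linked", "age", "noise", "const"))
  p <- setNames(res$p, res$covariate)
  expect_lt(p[["linked"]], 1e-6)
  expect_lt(p[["age"]], 1e-4)
  expect_gt(p[["noise"]], 0.01)
  expect_equal(p[["const"]], 1)
  expect_equal(res$note[res$covariate == "const"], "constant covariate")
  expect_equal(res$type[res$covariate == "age"], "continuous")
  ## continuous branch equals a direct Wilcoxon test
  ref <- wilcox.test(md$age ~ factor(lab$cluster), exact = FALSE)$p.value
  expect_equal(unname(p[["age"]]), ref)
  expect_equal(res$padj, bh_adjust(res$p))
  expect_error(covariate_association(lab, md, "absent"), "absent")
  lab3 <- lab; lab3$cluster[1] <- "C"
  expect_error(covariate_association(lab3, md, "age"), "two assigned")
})
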