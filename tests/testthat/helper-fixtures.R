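## Shared fixtures and independent oracles used across the suite.

## small fast design for smoke-level pipeline checks
small_design <- function(seed = 101) {
  simulation_design(
    n_genes = 300, n_control = 6, n_groupA = 10, n_groupB = 8,
    n_shared_de = 40, n_specificA = 20, n_specificB = 20,
    lfc_magnitude = 1.5, dispersion = 0.1, n_batches = 2,
    batch_lfc_sd = 0.5, seed = seed
  )
}

## reference Lee-Seung multiplicative updates, written independently of
## nmf_fit: used as the lambda = 0 oracle
reference_lee_seung <- function(X, W, H, n_iter) {
  eps <- 1e-12
  for (i in seq_len(n_iter)) {
    W <- W * (X %*% t(H)) / (W %*% (H %*% t(H)) + eps)
    H <- H * (t(W) %*% X) / (t(W) %*% W %*% H + eps)
  }
  list(W = W, H = H)
}

## brute-force hypergeometric upper tail by enumeration of all draws
enumerate_hyper_p <- function(universe_size, set_size, n_draw, observed) {
  draws <- combn(universe_size, n_draw)
  in_set <- seq_len(set_size)          # wlog the first genes form the set
  overlaps <- apply(draws, 2L, function(d) sum(d %in% in_set))
  mean(overlaps >= observed)
}

## direct linear solve of the random-walk-with-restart stationary system
solve_rwr <- function(network, seeds, r) {
  A <- as.matrix(igraph::as_adjacency_matrix(
    network,
    attr = if ("weight" %in% igraph::edge_attr_names(network)) "weight" else NULL))
  P <- sweep(A, 2L, pmax(colSums(A), .Machine$double.eps), "/")
  nodes <- igraph::V(network)$name
  e <- setNames(numeric(length(nodes)), nodes)
  e[seeds] <- 1 / length(seeds)
  w <- solve(diag(length(nodes)) - (1 - r) * P, r * e)
  setNames(as.numeric(w / sum(w)), nodes)
}

## random connected gene network over given gene names
random_gene_network <- function(genes, p = 0.1, seed = 1) {
  set.seed(seed)
  n <- length(genes)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- genes
  comps <- igraph::components(g)
  if (comps$no > 1L) {
    anchor <- which(comps$membership == 1L)[1L]
    for (cid in seq_len(comps$no)[-1L]) {
      g <- igraph::add_edges(g, c(anchor, which(comps$membership == cid)[1L]))
    }
  }
  igraph::E(g)$weight <- 1
  g
}
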