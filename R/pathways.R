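## Gene-set over-representation (hypergeometric) and simplified active-
## subnetwork detection: nodes are weighted by a random walk with restart
## from a seed-gene list, subnetworks are grown greedily from local maxima
## of weight * |log2FC| with a sqrt-size score normalisation, and scored
## against a permutation null that re-grows subnetworks under shuffled
## fold changes.

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for enrichment of the DEG list within a stated
#' universe: `p = P(X >= overlap)` for a hypergeometric draw of
#' `|DEG| ` genes from the universe with `|set|` successes. P values are
#' BH-adjusted across sets.
#'
#' @param deg_genes character vector of differentially expressed genes.
#'   Genes outside the universe are dropped (their number is reported in
#'   the `n_dropped` attribute, with a warning).
#' @param sets named list of gene sets (e.g. from [read_gmt()]).
#' @param universe character vector of testable genes; defaults to the
#'   union of set members is NOT used - supply the DE-tested genes.
#' @return Data.frame (set, set_size, overlap, p, padj) sorted by p.
#' @export
ora <- function(deg_genes, sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) abort("empty universe")
  deg_in <- unique(intersect(deg_genes, universe))
  n_dropped <- length(unique(deg_genes)) - length(deg_in)
  if (n_dropped > 0L) {
    warning(n_dropped, " DEG(s) outside the universe were dropped")
  }
  N <- length(universe)
  n_draw <- length(deg_in)
  res <- lapply(names(sets), function(nm) {
    members <- intersect(unique(sets[[nm]]), universe)
    ov <- length(intersect(members, deg_in))
    p <- stats::phyper(ov - 1L, length(members), N - length(members),
                       n_draw, lower.tail = FALSE)
    data.frame(set = nm, set_size = length(members), overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- bh_adjust(out$p)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Random-walk-with-restart node weights
#'
#' Stationary distribution of `w = (1 - r) P w + r e`, where `P` is the
#' column-normalised (weighted) adjacency and `e` is uniform over the seed
#' genes. Solved by power iteration to an L1 residual below `tol`;
#' weights sum to 1.
#'
#' @param network an [igraph::graph] with gene-name vertices.
#' @param seed_genes genes the walk restarts from (at least one must be in
#'   the network).
#' @param restart_prob restart probability `r` in (0, 1\].
#' @param tol convergence residual.
#' @param max_iter iteration cap.
#' @return Named weight vector over all network nodes.
#' @export
rwr_weights <- function(network, seed_genes, restart_prob = 0.5,
                        tol = 1e-10, max_iter = 100000) {
  if (restart_prob <= 0 || restart_prob > 1) {
    abort("restart_prob must be in (0, 1]")
  }
  nodes <- igraph::V(network)$name
  seeds <- intersect(seed_genes, nodes)
  if (length(seeds) == 0L) abort("no seed gene is present in the network")
  A <- igraph::as_adjacency_matrix(network, attr =
    if ("weight" %in% igraph::edge_attr_names(network)) "weight" else NULL,
    sparse = TRUE)
  cs <- Matrix::colSums(A)
  e <- setNames(numeric(length(nodes)), nodes)
  e[seeds] <- 1 / length(seeds)
  w <- e
  nonzero <- cs > 0
  inv_cs <- ifelse(nonzero, 1 / cs, 0)
  for (i in seq_len(max_iter)) {
    ## dangling columns restart: their outgoing mass returns to the seeds
    dangling <- sum(w[!nonzero])
    w_new <- (1 - restart_prob) *
      (as.numeric(A %*% (w * inv_cs)) + dangling * e) + restart_prob * e
    if (sum(abs(w_new - w)) < tol) { w <- w_new; break }
    w <- w_new
  }
  w <- w / sum(w)
  setNames(as.numeric(w), nodes)
}

## greedy subnetwork growth from a start node on node values v;
## adj: adjacency list of integer neighbours. Stops when no positive score
## gain (unless force = TRUE) or at max_size.
grow_subnetwork <- function(start, v, adj, max_size, force = FALSE) {
  members <- start
  total <- v[start]
  score <- total               # total / sqrt(1)
  in_set <- logical(length(v)); in_set[start] <- TRUE
  boundary <- setdiff(adj[[start]], members)
  while (length(members) < max_size && length(boundary) > 0L) {
    cand_scores <- (total + v[boundary]) / sqrt(length(members) + 1)
    best <- which.max(cand_scores)
    if (!force && cand_scores[best] <= score) break
    nb <- boundary[best]
    members <- c(members, nb)
    in_set[nb] <- TRUE
    total <- total + v[nb]
    score <- total / sqrt(length(members))
    boundary <- unique(c(boundary[-best], adj[[nb]][!in_set[adj[[nb]]]]))
  }
  list(members = members, score = score)
}

## local maxima of v over the adjacency list (strictly positive values
## that are >= all neighbour values)
local_maxima <- function(v, adj) {
  which(vapply(seq_along(v), function(i) {
    v[i] > 0 && (length(adj[[i]]) == 0L || v[i] >= max(v[adj[[i]]]))
  }, logical(1L)))
}

## best greedy subnetwork over all local maxima of v (size-capped);
## returns score only (used by the permutation null)
best_grown_score <- function(v, adj, max_size, force = FALSE) {
  starts <- local_maxima(v, adj)
  if (length(starts) == 0L) return(0)
  max(vapply(starts, function(s) {
    grow_subnetwork(s, v, adj, max_size, force = force)$score
  }, 0))
}

#' Detect active subnetworks of differential expression
#'
#' Scores connected subgraphs by the summed `weight * |log2FC|` of their
#' nodes, normalised by the square root of their size. Candidate
#' subnetworks are grown greedily from each local maximum of the node
#' value, near-duplicates (Jaccard overlap above `dedup_jaccard`) are
#' collapsed keeping the higher score, and each reported subnetwork
#' receives a permutation p value: the fraction of fold-change
#' permutations whose best re-grown subnetwork (same growth rule and size
#' cap) scores at least as high. Comparing every subnetwork against the
#' permutation maximum makes the top-ranked p value exactly uniform under
#' the null and lower ranks conservative. P values are BH-adjusted across
#' reported subnetworks.
#'
#' @param network an [igraph::graph] with gene-name vertices.
#' @param de a `de_result` (or named log2 fold-change vector). Nodes
#'   without a fold change are weighted 0; at least half the nodes must be
#'   covered.
#' @param node_weights optional named node weights (e.g. from
#'   [rwr_weights()]); defaults to uniform.
#' @param max_size maximum subnetwork size.
#' @param n_perm number of fold-change permutations (values below 100
#'   trigger a warning; 0 is an error).
#' @param seed RNG seed for the permutations.
#' @param dedup_jaccard overlap threshold for collapsing near-duplicates.
#' @param max_report cap on the number of reported subnetworks.
#' @return Data.frame of class `subnetwork_results`: rank, nodes
#'   (comma-separated), size, score, perm_p, padj; per-node values are in
#'   the `node_values` attribute.
#' @export
find_subnetworks <- function(network, de, node_weights = NULL, max_size = 30,
                             n_perm = 1000, seed = 1, dedup_jaccard = 0.5,
                             max_report = 10) {
  if (n_perm == 0L) abort("n_perm must be positive")
  if (n_perm < 100L) warning("n_perm below 100 gives coarse p values")
  nodes <- igraph::V(network)$name
  lfc_all <- if (inherits(de, "de_result") || is.data.frame(de)) {
    setNames(de$log2FC, de$gene)
  } else de
  covered <- nodes %in% names(lfc_all)
  if (mean(covered) < 0.5) {
    abort("fold changes available for under half the network nodes")
  }
  lfc <- setNames(numeric(length(nodes)), nodes)
  lfc[nodes[covered]] <- lfc_all[nodes[covered]]
  wt <- setNames(rep(1, length(nodes)), nodes)
  if (!is.null(node_weights)) {
    common <- intersect(names(node_weights), nodes)
    wt[] <- 0
    wt[common] <- node_weights[common]
  }
  v <- wt * abs(lfc)

  adj <- igraph::as_adj_list(network)
  adj <- lapply(adj, as.integer)

  starts <- local_maxima(v, adj)
  grown <- lapply(starts, grow_subnetwork, v = v, adj = adj,
                  max_size = max_size)
  if (length(grown) == 0L) {
    out <- data.frame(rank = integer(), nodes = character(),
                      size = integer(), score = numeric(),
                      perm_p = numeric(), padj = numeric())
    class(out) <- c("subnetwork_results", class(out))
    return(out)
  }
  ord <- order(vapply(grown, `[[`, 0, "score"), decreasing = TRUE)
  grown <- grown[ord]
  kept <- list()
  for (g in grown) {
    dup <- any(vapply(kept, function(kg) {
      length(intersect(kg$members, g$members)) /
        length(union(kg$members, g$members)) > dedup_jaccard
    }, logical(1L)))
    if (!dup) kept[[length(kept) + 1L]] <- g
    if (length(kept) >= max_report) break
  }

  ## permutation null: the maximum greedily grown score under the same size
  ## cap as the observed run. For the top-ranked subnetwork this compares
  ## like with like (max statistic vs max statistic), so its p value is
  ## exactly uniform under exchangeable fold changes; lower ranks are
  ## compared against the same null maximum and are therefore conservative.
  set.seed(seed)
  sizes <- vapply(kept, function(g) length(g$members), 1L)
  null_scores <- vapply(seq_len(n_perm), function(p) {
    vp <- wt * abs(sample(lfc))
    best_grown_score(vp, adj, max_size = max_size)
  }, 0)
  perm_p <- vapply(seq_along(kept), function(j) {
    obs <- kept[[j]]$score
    if (obs <= 0) return(1)
    (1 + sum(null_scores >= obs)) / (n_perm + 1)
  }, 0)

  out <- data.frame(
    rank = seq_along(kept),
    nodes = vapply(kept, function(g) paste(nodes[g$members], collapse = ","), ""),
    size = sizes,
    score = vapply(kept, `[[`, 0, "score"),
    perm_p = perm_p,
    padj = bh_adjust(perm_p),
    stringsAsFactors = FALSE
  )
  attr(out, "node_values") <- data.frame(
    gene = nodes, weight = as.numeric(wt), log2FC = as.numeric(lfc),
    value = as.numeric(v), stringsAsFactors = FALSE)
  class(out) <- c("subnetwork_results", class(out))
  out
}
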