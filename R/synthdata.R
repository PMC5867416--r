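## Synthetic cohort generator. Emulates the statistical structure the
## downstream analysis assumes: negative-binomial counts for a control arm
## plus two OA subgroups, planted shared and subgroup-specific fold changes,
## gene-wise batch shifts, uneven library depths, and an interaction network
## whose dense modules overlap the planted marker genes.

#' Describe a synthetic cohort design
#'
#' Parameters of the simulated study. The defaults mirror the shape of the
#' cartilage cohort the package is modelled on: 10 non-OA controls and two
#' OA subgroups of 24 and 18 patients, with several hundred planted
#' differentially expressed genes at a one-unit log2 fold change.
#'
#' @param n_genes number of genes.
#' @param n_control,n_groupA,n_groupB samples per arm.
#' @param n_shared_de genes differentially expressed in both OA subgroups
#'   versus control.
#' @param n_specificA,n_specificB genes perturbed only in subgroup A or B.
#' @param lfc_magnitude absolute planted log2 fold change.
#' @param dispersion negative-binomial dispersion alpha, with
#'   `Var = mu + alpha * mu^2`.
#' @param baseline_mean_log_range log10 range baseline means are drawn from.
#' @param n_batches number of processing batches (balanced across arms).
#' @param batch_lfc_sd standard deviation of gene-wise additive log2 batch
#'   shifts, applied to a random 20 percent of genes.
#' @param seed integer RNG seed.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(n_genes = 2000, n_control = 10, n_groupA = 24,
                              n_groupB = 18, n_shared_de = 300,
                              n_specificA = 150, n_specificB = 150,
                              lfc_magnitude = 1, dispersion = 0.1,
                              baseline_mean_log_range = c(0.5, 3.5),
                              n_batches = 2, batch_lfc_sd = 0.5, seed = 1) {
  d <- list(
    n_genes = as.integer(n_genes), n_control = as.integer(n_control),
    n_groupA = as.integer(n_groupA), n_groupB = as.integer(n_groupB),
    n_shared_de = as.integer(n_shared_de),
    n_specificA = as.integer(n_specificA),
    n_specificB = as.integer(n_specificB),
    lfc_magnitude = lfc_magnitude, dispersion = dispersion,
    baseline_mean_log_range = baseline_mean_log_range,
    n_batches = as.integer(n_batches), batch_lfc_sd = batch_lfc_sd,
    seed = as.integer(seed)
  )
  with(d, {
    if (n_genes < 1L || n_control < 1L || n_groupA < 1L || n_groupB < 1L)
      abort("all arm and gene counts must be positive")
    if (n_shared_de < 0L || n_specificA < 0L || n_specificB < 0L)
      abort("planted gene counts must be non-negative")
    if (n_shared_de + n_specificA + n_specificB > n_genes)
      abort("infeasible design: more planted DE genes than genes")
    if (dispersion <= 0) abort("dispersion must be positive")
    if (n_batches < 1L) abort("n_batches must be >= 1")
    if (batch_lfc_sd < 0) abort("batch_lfc_sd must be non-negative")
    if (length(baseline_mean_log_range) != 2L ||
        diff(baseline_mean_log_range) < 0)
      abort("baseline_mean_log_range must be an increasing pair")
  })
  structure(d, class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  cat("Synthetic cohort design:", x$n_genes, "genes;",
      x$n_control, "control +", x$n_groupA, "A +", x$n_groupB, "B samples\n")
  cat("  planted DE:", x$n_shared_de, "shared,", x$n_specificA, "A-specific,",
      x$n_specificB, "B-specific at |lfc| =", x$lfc_magnitude, "\n")
  cat("  NB dispersion:", x$dispersion, " batches:", x$n_batches,
      " batch sd:", x$batch_lfc_sd, " seed:", x$seed, "\n")
  invisible(x)
}

#' Simulate a count matrix with planted subgroup structure
#'
#' Counts are drawn gene-wise from a negative binomial with
#' `Var = mu + alpha * mu^2`, where the mean combines a log10-uniform
#' baseline, the planted log2 fold change of the sample's arm, a gene-wise
#' batch shift and a log-uniform library-size factor in \[0.5, 2\].
#' Output is bit-identical for a fixed seed.
#'
#' @param design a [simulation_design()].
#' @return A list of class `oa_simulation` with elements `counts` (integer
#'   gene x sample matrix), `metadata` (sample, condition, group, batch) and
#'   `truth` (planted ground truth: arm labels, signed planted fold changes,
#'   batch assignment, secreted gene set).
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed)
  n_genes <- design$n_genes
  genes <- sprintf("g%05d", seq_len(n_genes))
  samples <- c(
    sprintf("ctrl_%02d", seq_len(design$n_control)),
    sprintf("A_%02d", seq_len(design$n_groupA)),
    sprintf("B_%02d", seq_len(design$n_groupB))
  )
  arm <- rep(c("control", "A", "B"),
             c(design$n_control, design$n_groupA, design$n_groupB))
  n_samples <- length(samples)

  baseline <- 10^runif(n_genes, design$baseline_mean_log_range[1L],
                       design$baseline_mean_log_range[2L])

  n_planted <- design$n_shared_de + design$n_specificA + design$n_specificB
  planted_idx <- sample.int(n_genes, n_planted)
  shared_idx <- planted_idx[seq_len(design$n_shared_de)]
  specA_idx <- planted_idx[design$n_shared_de + seq_len(design$n_specificA)]
  specB_idx <- planted_idx[design$n_shared_de + design$n_specificA +
                             seq_len(design$n_specificB)]
  signed_lfc <- function(idx) {
    setNames(sample(c(-1, 1), length(idx), replace = TRUE) *
               design$lfc_magnitude, genes[idx])
  }
  lfc_shared <- signed_lfc(shared_idx)
  lfc_A <- signed_lfc(specA_idx)
  lfc_B <- signed_lfc(specB_idx)

  ## per-gene log2 shift for each arm
  shift_A <- shift_B <- numeric(n_genes)
  shift_A[shared_idx] <- shift_A[shared_idx] + lfc_shared
  shift_B[shared_idx] <- shift_B[shared_idx] + lfc_shared
  shift_A[specA_idx] <- shift_A[specA_idx] + lfc_A
  shift_B[specB_idx] <- shift_B[specB_idx] + lfc_B

  ## balanced batch assignment within each arm keeps batches correctable
  batch <- integer(n_samples)
  for (a in unique(arm)) {
    idx <- which(arm == a)
    batch[idx] <- rep_len(seq_len(design$n_batches), length(idx))
  }
  batch_affected <- sample.int(n_genes, round(0.2 * n_genes))
  batch_shift <- matrix(0, n_genes, design$n_batches)
  if (design$n_batches > 1L && design$batch_lfc_sd > 0) {
    batch_shift[batch_affected, ] <- rnorm(
      length(batch_affected) * design$n_batches, 0, design$batch_lfc_sd)
  }

  depth <- exp(runif(n_samples, log(0.5), log(2)))

  counts <- matrix(0L, n_genes, n_samples, dimnames = list(genes, samples))
  size <- 1 / design$dispersion
  for (j in seq_len(n_samples)) {
    shift <- switch(arm[j], control = 0, A = shift_A, B = shift_B)
    mu <- baseline * 2^(shift + batch_shift[, batch[j]]) * depth[j]
    counts[, j] <- rnbinom(n_genes, mu = mu, size = size)
  }
  storage.mode(counts) <- "integer"

  ## secreted annotation: half the subgroup-discriminating genes plus decoys
  diff_genes <- genes[c(specA_idx, specB_idx)]
  secreted_true <- sample(diff_genes, ceiling(length(diff_genes) / 2))
  decoy_pool <- setdiff(genes, genes[planted_idx])
  decoys <- sample(decoy_pool, min(length(decoy_pool), length(secreted_true)))
  secreted <- sort(c(secreted_true, decoys))

  metadata <- data.frame(
    sample = samples,
    condition = ifelse(arm == "control", "nonOA", "OA"),
    group = ifelse(arm == "control", NA_character_, arm),
    batch = batch,
    stringsAsFactors = FALSE
  )
  truth <- list(
    gene_ids = genes,
    sample_labels = setNames(arm, samples),
    de_genes_shared = lfc_shared,
    de_genes_A = lfc_A,
    de_genes_B = lfc_B,
    batch_assignment = setNames(batch, samples),
    baseline_mean = setNames(baseline, genes),
    depth_factor = setNames(depth, samples),
    secreted_genes = secreted
  )
  structure(list(counts = counts, metadata = metadata, truth = truth,
                 design = design),
            class = "oa_simulation")
}

#' @export
print.oa_simulation <- function(x, ...) {
  cat("Simulated cohort:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples (", sum(x$metadata$condition == "nonOA"), "non-OA )\n")
  invisible(x)
}

#' Simulate a gene interaction network with planted modules
#'
#' Builds an undirected weighted graph over gene identifiers in which each
#' planted differentially expressed gene set forms a dense module (edge
#' probability `module_density`) over a sparse random background; extra
#' edges are added if needed so the graph is connected.
#'
#' @param truth ground truth from [simulate_counts()].
#' @param n_nodes number of genes in the network (planted genes always
#'   included; must be at least their number).
#' @param module_density within-module edge probability in (0, 1\].
#' @param background_degree expected background degree per node.
#' @param seed integer RNG seed.
#' @return An undirected weighted [igraph::graph].
#' @export
simulate_network <- function(truth, n_nodes = length(truth$gene_ids),
                             module_density = 0.1, background_degree = 2,
                             seed = 1) {
  if (module_density <= 0 || module_density > 1)
    abort("module_density must be in (0, 1]")
  modules <- list(names(truth$de_genes_shared), names(truth$de_genes_A),
                  names(truth$de_genes_B))
  planted <- unique(unlist(modules))
  if (n_nodes < length(planted))
    abort("n_nodes (", n_nodes, ") smaller than number of planted genes (",
          length(planted), ")")
  set.seed(seed)
  others <- setdiff(truth$gene_ids, planted)
  nodes <- c(planted, sample(others, n_nodes - length(planted)))

  edges <- list()
  for (mod in modules) {
    if (length(mod) < 2L) next
    pairs <- combn(mod, 2L)
    keep <- runif(ncol(pairs)) <= module_density
    if (any(keep)) edges[[length(edges) + 1L]] <- pairs[, keep, drop = FALSE]
  }
  if (background_degree > 0 && length(nodes) > 1L) {
    n_bg <- round(background_degree * length(nodes) / 2)
    if (n_bg > 0) {
      bg <- replicate(n_bg, sample(nodes, 2L))
      edges[[length(edges) + 1L]] <- bg
    }
  }
  el <- if (length(edges)) t(do.call(cbind, edges)) else
    matrix(character(), 0, 2)
  g <- igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  g <- igraph::simplify(g)
  ## spanning augmentation keeps the graph connected
  comps <- igraph::components(g)
  if (comps$no > 1L) {
    anchor <- which(comps$membership == 1L)[1L]
    link_to <- vapply(seq_len(comps$no)[-1L], function(cid) {
      which(comps$membership == cid)[1L]
    }, 1L)
    g <- igraph::add_edges(g, rbind(rep(anchor, length(link_to)), link_to))
  }
  igraph::E(g)$weight <- 1
  g
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Emits the counts TSV, metadata TSV, network edge list, GMT collection
#' (planted DE sets named `planted_shared`, `planted_A`, `planted_B`, plus
#' random sets), secreted-gene list and ground-truth JSON, and a manifest
#' describing every file. The files round-trip losslessly through the
#' package's readers.
#'
#' @param dir_path output directory (created if absent).
#' @param design a [simulation_design()].
#' @param module_density,background_degree network parameters, see
#'   [simulate_network()].
#' @param n_random_sets number of random decoy gene sets in the GMT.
#' @return The manifest as a data.frame (invisibly also written as JSON).
#' @export
write_fixture_bundle <- function(dir_path, design, module_density = 0.1,
                                 background_degree = 2, n_random_sets = 5) {
  ok <- dir.exists(dir_path) || dir.create(dir_path, recursive = TRUE)
  if (!ok) abort("cannot create directory ", dir_path)
  sim <- simulate_counts(design)
  net <- simulate_network(sim$truth, module_density = module_density,
                          background_degree = background_degree,
                          seed = stage_seed(design$seed, "network"))
  paths <- file.path(dir_path, c(
    counts = "counts.tsv", metadata = "metadata.tsv", network = "network.tsv",
    gmt = "genesets.gmt", secreted = "secreted.txt", truth = "truth.json"
  ))
  names(paths) <- c("counts", "metadata", "network", "gmt", "secreted", "truth")

  write_counts_tsv(sim$counts, paths[["counts"]])
  write_tsv(sim$metadata, paths[["metadata"]])
  write_network_tsv(net, paths[["network"]])

  sets <- list(
    planted_shared = names(sim$truth$de_genes_shared),
    planted_A = names(sim$truth$de_genes_A),
    planted_B = names(sim$truth$de_genes_B)
  )
  set.seed(stage_seed(design$seed, "pathways"))
  for (i in seq_len(n_random_sets)) {
    sets[[sprintf("random_set_%02d", i)]] <-
      sample(sim$truth$gene_ids, min(50L, design$n_genes))
  }
  write_gmt(sets, paths[["gmt"]])
  write_gene_list(sim$truth$secreted_genes, paths[["secreted"]])
  jsonlite::write_json(
    list(sample_labels = as.list(sim$truth$sample_labels),
         de_genes_shared = as.list(sim$truth$de_genes_shared),
         de_genes_A = as.list(sim$truth$de_genes_A),
         de_genes_B = as.list(sim$truth$de_genes_B),
         batch_assignment = as.list(sim$truth$batch_assignment),
         secreted_genes = sim$truth$secreted_genes),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)

  manifest <- data.frame(
    file = basename(paths),
    role = names(paths),
    n_rows = c(nrow(sim$counts), nrow(sim$metadata),
               igraph::ecount(net), length(sets),
               length(sim$truth$secreted_genes), NA),
    n_cols = c(ncol(sim$counts) + 1L, ncol(sim$metadata), 3L, NA, 1L, NA),
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(manifest, file.path(dir_path, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
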