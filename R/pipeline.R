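## End-to-end orchestration: preprocess -> DE (OA vs non-OA) -> stratify
## (OA samples only) -> per-group DE -> classifier panel -> pathway and
## subnetwork reports -> secreted biomarkers. One root seed feeds named
## substreams, so a re-run with the same configuration reproduces every
## stochastic stage exactly.

pipeline_defaults <- function() {
  list(
    counts = NULL, metadata = NULL, network = NULL, gmt = NULL,
    secreted = NULL, output_dir = NULL,
    fc_min = 1.5, fdr_max = 0.10, pseudocount = 1, min_total = 10,
    top_n = 2000, k_min = 2, k_max = 5, n_runs = 500, lambda = 1.0,
    subsample_fraction = 0.8, min_silhouette = 0,
    panel_size = 10, folds = 5, svm_cost = 1,
    max_subnetwork_size = 30, n_perm = 1000, n_seed_genes = 20,
    restart_prob = 0.5,
    do_classify = TRUE, do_pathways = TRUE, do_biomarkers = TRUE,
    seed = 1
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list of flat key-value settings,
#' fills in defaults, rejects unknown and duplicated keys, checks
#' parameter ranges and verifies that every referenced input file exists.
#'
#' @param config file path or named list.
#' @return The normalised configuration list (class `pipeline_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort("config file not found: ", config)
    lines <- readLines(config, warn = FALSE)
    keys <- sub(":.*$", "", grep("^[A-Za-z_][A-Za-z0-9_]*\\s*:", lines,
                                 value = TRUE))
    dup <- unique(keys[duplicated(keys)])
    if (length(dup)) abort("duplicate config key(s): ",
                           paste(dup, collapse = ", "))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a file path or a named list")
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) abort("unknown config key(s): ",
                             paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, config)

  errs <- character()
  need <- function(key) {
    if (is.null(cfg[[key]])) errs <<- c(errs, paste0(key, ": required"))
  }
  need("counts"); need("metadata"); need("output_dir")
  if (isTRUE(cfg$do_pathways)) { need("gmt"); need("network") }
  if (cfg$lambda > 0) need("network")
  if (isTRUE(cfg$do_biomarkers)) need("secreted")
  for (key in c("counts", "metadata", "network", "gmt", "secreted")) {
    p <- cfg[[key]]
    if (!is.null(p) && !file.exists(p)) {
      errs <- c(errs, paste0(key, ": file not found (", p, ")"))
    }
  }
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(cfg$fc_min >= 1, "fc_min: must be >= 1")
  chk(cfg$fdr_max > 0 && cfg$fdr_max <= 1, "fdr_max: must be in (0, 1]")
  chk(cfg$pseudocount > 0, "pseudocount: must be positive")
  chk(cfg$top_n >= 10, "top_n: must be >= 10")
  chk(cfg$k_min >= 2 && cfg$k_max >= cfg$k_min, "k_min/k_max: need 2 <= k_min <= k_max")
  chk(cfg$n_runs >= 2, "n_runs: must be >= 2")
  chk(cfg$lambda >= 0, "lambda: must be non-negative")
  chk(cfg$subsample_fraction > 0 && cfg$subsample_fraction <= 1,
      "subsample_fraction: must be in (0, 1]")
  chk(cfg$min_silhouette >= -1 && cfg$min_silhouette <= 1,
      "min_silhouette: must be in [-1, 1]")
  chk(cfg$panel_size >= 1, "panel_size: must be >= 1")
  chk(cfg$folds >= 2, "folds: must be >= 2")
  chk(cfg$n_perm >= 1, "n_perm: must be >= 1")
  chk(cfg$restart_prob > 0 && cfg$restart_prob <= 1,
      "restart_prob: must be in (0, 1]")
  if (length(errs)) abort("invalid configuration:\n  ",
                          paste(errs, collapse = "\n  "))
  structure(cfg, class = "pipeline_config")
}

pipeline_log <- function(con, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full stratification pipeline
#'
#' Executes preprocessing, OA-versus-control differential expression,
#' consensus stratification of the OA samples, per-group differential
#' expression, classifier-panel derivation, pathway and subnetwork
#' analysis and biomarker nomination, writing every intermediate artefact
#' plus a manifest (parameters, per-stage seeds, input and output
#' checksums) to the configured output directory. A stage failure aborts
#' with the stage name; artefacts of completed stages persist.
#'
#' @param config a `pipeline_config`, config list, or YAML path (validated
#'   with [validate_config()]).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  out_dir <- cfg$output_dir
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    abort("cannot create output directory ", out_dir)
  }
  log_con <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  outputs <- character()
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    outputs[[name]] <<- path
    path
  }
  stage <- "setup"
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      abort("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  ## ---- preprocess -------------------------------------------------------
  run_stage("preprocess", {
    counts <- read_counts_tsv(cfg$counts)
    metadata <- read_metadata_tsv(cfg$metadata)
    if (!setequal(metadata$sample, colnames(counts))) {
      abort("metadata samples do not match count matrix columns")
    }
    metadata <- metadata[match(colnames(counts), metadata$sample), ]
    pipeline_log(log_con, "preprocess",
                 sprintf("%d genes x %d samples", nrow(counts), ncol(counts)))
    sf <- size_factors(counts)
    expr <- normalize_log(counts, sf, pseudocount = cfg$pseudocount,
                          min_total = cfg$min_total)
    n_batches <- length(unique(metadata$batch))
    if (n_batches > 1L) expr <- batch_correct(expr, metadata$batch)
    pca <- pca_embed(expr, n_components = min(5L, ncol(expr) - 1L))
    emit("pca.tsv", function(p) write_tsv(data.frame(
      sample = rownames(pca$coords), pca$coords, check.names = FALSE), p))
  })

  ## ---- OA vs control DE -------------------------------------------------
  run_stage("de", {
    cond <- factor(metadata$condition, levels = c("nonOA", "OA"))
    de_all <- de_test(counts, cond, fc_min = cfg$fc_min, fdr_max = cfg$fdr_max)
    pipeline_log(log_con, "de", sprintf("OA vs nonOA: %d DEGs of %d genes",
                                        sum(de_all$is_deg), nrow(de_all)))
    emit("de_OA_vs_nonOA.tsv", function(p) write_de_tsv(de_all, p))
  })

  ## ---- stratify (OA samples only) --------------------------------------
  run_stage("stratify", {
    oa <- metadata$condition == "OA"
    network <- if (!is.null(cfg$network)) read_network_tsv(cfg$network)
    X <- clustering_matrix(expr[, oa, drop = FALSE], top_n = cfg$top_n)
    consensus <- select_k(
      X, k_range = seq(cfg$k_min, cfg$k_max), n_runs = cfg$n_runs,
      lambda = cfg$lambda, network = network,
      subsample_fraction = cfg$subsample_fraction,
      seed = stage_seed(cfg$seed, "stratify"))
    assign <- assign_with_exclusion(consensus, cfg$min_silhouette)
    ## name groups by decreasing size: largest assigned cluster is "A"
    sizes <- sort(table(assign$cluster[!assign$excluded]), decreasing = TRUE)
    rename <- setNames(LETTERS[seq_along(sizes)], names(sizes))
    assign$group <- ifelse(assign$excluded, "unassigned",
                           rename[assign$cluster])
    pipeline_log(log_con, "stratify", sprintf(
      "chosen k = %d; groups: %s; %d unassigned", consensus$chosen_k,
      paste(rename, as.integer(sizes), sep = "=", collapse = ", "),
      sum(assign$excluded)))
    emit("coclustering.tsv", function(p) write_tsv(data.frame(
      sample = consensus$samples, consensus$coclustering,
      check.names = FALSE), p))
    emit("per_k_silhouette.tsv", function(p) write_tsv(data.frame(
      k = as.integer(names(consensus$per_k_mean_silhouette)),
      mean_silhouette = as.numeric(consensus$per_k_mean_silhouette)), p))
    emit("labels.tsv", function(p) write_tsv(
      assign[, c("sample", "group", "cluster", "silhouette", "excluded")], p))
  })

  ## ---- per-group DE -----------------------------------------------------
  run_stage("group_de", {
    grp <- setNames(assign$group, assign$sample)
    group_of <- function(s) {
      ifelse(metadata$condition == "nonOA", "nonOA",
             grp[metadata$sample])
    }
    gvec <- group_of(metadata$sample)
    contrasts <- list(
      A_vs_nonOA = c("nonOA", "A"), B_vs_nonOA = c("nonOA", "B"),
      A_vs_B = c("A", "B"))
    de_group <- list()
    for (nm in names(contrasts)) {
      lv <- contrasts[[nm]]
      sel <- gvec %in% lv
      de_group[[nm]] <- de_test(counts[, sel, drop = FALSE],
                                factor(gvec[sel], levels = lv),
                                fc_min = cfg$fc_min, fdr_max = cfg$fdr_max)
      emit(paste0("de_", nm, ".tsv"),
           local({ d <- de_group[[nm]]; function(p) write_de_tsv(d, p) }))
    }
    overlap <- compare_deg_sets(de_all, de_group$A_vs_nonOA,
                                de_group$B_vs_nonOA)
    pipeline_log(log_con, "group_de", sprintf(
      "distinctive DEGs: A %d, B %d, shared %d",
      overlap$summary[["distinctive_A"]], overlap$summary[["distinctive_B"]],
      overlap$summary[["shared_AB"]]))
    emit("deg_overlap.tsv", function(p) write_tsv(data.frame(
      quantity = names(overlap$summary),
      count = as.integer(overlap$summary)), p))
  })

  ## ---- classifier panel -------------------------------------------------
  if (isTRUE(cfg$do_classify)) run_stage("classify", {
    keep <- assign$group %in% c("A", "B")
    expr_oa <- expr[, match(assign$sample[keep], colnames(expr)),
                    drop = FALSE]
    labels <- assign$group[keep]
    stats <- nsc_statistics(expr_oa, labels)
    panel <- select_panel_size(stats, cfg$panel_size)
    model <- train_panel_classifier(
      expr_oa, labels, panel, folds = cfg$folds, cost = cfg$svm_cost,
      seed = stage_seed(cfg$seed, "classify"))
    pipeline_log(log_con, "classify", sprintf(
      "%d-gene panel; %d-fold CV AUC = %.3f", length(panel$genes),
      cfg$folds, model$cv_auc))
    emit("panel.tsv", function(p) write_tsv(data.frame(
      gene = panel$genes,
      panel$d_shrunk,
      rank = seq_along(panel$genes), check.names = FALSE), p))
    emit("classifier.json", function(p) write_classifier_json(model, p))
  })

  ## ---- pathways ---------------------------------------------------------
  if (isTRUE(cfg$do_pathways)) run_stage("pathways", {
    sets <- read_gmt(cfg$gmt)
    ora_tabs <- lapply(names(de_group), function(nm) {
      tab <- ora(deg_genes(de_group[[nm]]), sets, de_group[[nm]]$gene)
      cbind(contrast = nm, tab)
    })
    emit("ora.tsv", function(p) write_tsv(do.call(rbind, ora_tabs), p))
    de_ab <- de_group$A_vs_B
    deg_tab <- de_ab[de_ab$is_deg, , drop = FALSE]
    seeds <- head(deg_tab$gene[order(deg_tab$padj, -abs(deg_tab$log2FC))],
                  cfg$n_seed_genes)
    if (length(seeds) == 0L) {
      pipeline_log(log_con, "pathways", "no A-vs-B DEGs; skipping subnetworks")
    } else {
      weights <- rwr_weights(network, seeds, restart_prob = cfg$restart_prob)
      subnets <- find_subnetworks(
        network, de_ab, node_weights = weights,
        max_size = cfg$max_subnetwork_size, n_perm = cfg$n_perm,
        seed = stage_seed(cfg$seed, "pathways"))
      pipeline_log(log_con, "pathways", sprintf(
        "%d subnetworks reported (top score %.3f)", nrow(subnets),
        if (nrow(subnets)) subnets$score[1L] else NA))
      emit("subnetworks.tsv", function(p) write_tsv(as.data.frame(subnets), p))
      emit("subnetwork_nodes.tsv", function(p) write_tsv(
        attr(subnets, "node_values"), p))
    }
  })

  ## ---- biomarkers -------------------------------------------------------
  if (isTRUE(cfg$do_biomarkers)) run_stage("biomarkers", {
    secreted <- read_gene_list(cfg$secreted)
    bm <- secreted_biomarkers(de_group$A_vs_B, secreted)
    pipeline_log(log_con, "biomarkers", sprintf(
      "%d secreted biomarker candidates", nrow(bm)))
    emit("biomarkers.tsv", function(p) write_biomarker_report(bm, p))
  })

  ## ---- manifest ---------------------------------------------------------
  stage <- "manifest"
  input_paths <- Filter(Negate(is.null),
                        cfg[c("counts", "metadata", "network", "gmt",
                              "secreted")])
  manifest <- list(
    package_version = as.character(utils::packageVersion("oastrat")),
    parameters = cfg[setdiff(names(cfg),
                             c("counts", "metadata", "network", "gmt",
                               "secreted", "output_dir"))],
    seed = cfg$seed,
    stage_seeds = sapply(c("stratify", "classify", "pathways"),
                         function(s) stage_seed(cfg$seed, s),
                         simplify = FALSE),
    inputs = lapply(input_paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(outputs, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log(log_con, "done",
               sprintf("%d artefacts written", length(outputs) + 2L))
  invisible(manifest)
}
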