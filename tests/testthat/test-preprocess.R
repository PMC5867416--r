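test_that("size factors implement median-of-ratios", {
  ## identical samples normalise to 1
  m <- matrix(c(10L, 20L, 30L), 3, 4, dimnames = list(paste0("g", 1:3),
                                                      paste0("s", 1:4)))
  expect_equal(unname(size_factors(m)), rep(1, 4))

  ## doubling one sample doubles its factor
  m2 <- m; m2[, 2] <- 2L * m2[, 2]
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)

  ## hand-computed 3 genes x 2 samples toy
  toy <- matrix(c(2L, 8L, 6L, 8L, 2L, 6L), 3, 2,
                dimnames = list(paste0("g", 1:3), c("a", "b")))
  geo <- exp(rowMeans(log(toy)))
  expected <- apply(toy / geo, 2L, median)
  expect_equal(size_factors(toy), expected)

  ## gene reordering leaves factors unchanged
  perm <- c(3L, 1L, 2L)
  expect_equal(size_factors(toy[perm, ]), size_factors(toy))

  m3 <- m; m3[, 3] <- 0L
  expect_error(size_factors(m3), "s3")
})

test_that("log normalisation removes depth differences", {
  m <- matrix(c(0L, 7L, 3L, 15L), 2, 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  expr <- normalize_log(m, factors = c(1, 1), pseudocount = 1, min_total = 0)
  expect_equal(expr["g1", "a"], 0)     # log2(0 + 1)
  expect_equal(expr["g2", "a"], 3)     # log2(7 + 1)
  expect_error(normalize_log(m, pseudocount = 0), "pseudocount")

  ## a depth-scaled duplicate sample becomes identical after normalisation
  set.seed(1)
  base <- matrix(rpois(300, 60), 100, 3)
  dup <- cbind(base, 3L * base[, 3])
  rownames(dup) <- paste0("g", 1:100)
  colnames(dup) <- paste0("s", 1:4)
  expr2 <- normalize_log(dup, min_total = 0)
  expect_equal(unname(expr2[, 3]), unname(expr2[, 4]), tolerance = 1e-12)
})

test_that("batch correction equalises batch means and reduces batch structure", {
  set.seed(2)
  x <- matrix(rnorm(50 * 12, 8), 50, 12,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:12)))
  ## single batch: identity
  expect_equal(batch_correct(x, rep(1, 12)), x)
  expect_error(batch_correct(x, c(rep(1, 11), 2)), "singleton")

  batch <- rep(1:2, each = 6)
  shifted <- x; shifted[1:10, batch == 2] <- shifted[1:10, batch == 2] + 3
  corr <- batch_correct(shifted, batch)
  m1 <- rowMeans(corr[, batch == 1]); m2 <- rowMeans(corr[, batch == 2])
  expect_equal(m1, m2, tolerance = 1e-12)

  ## on simulated data, batch separation in PC space drops after correction
  d <- simulation_design(n_genes = 400, n_control = 8, n_groupA = 8,
                         n_groupB = 8, n_shared_de = 0, n_specificA = 0,
                         n_specificB = 0, n_batches = 2, batch_lfc_sd = 1,
                         seed = 21)
  sim <- simulate_counts(d)
  expr <- normalize_log(sim$counts)
  pc_raw <- pca_embed(expr, 2)$coords
  pc_cor <- pca_embed(batch_correct(expr, sim$metadata$batch), 2)$coords
  sil <- function(coords) {
    mean(silhouette_widths(as.matrix(dist(coords)), sim$metadata$batch))
  }
  expect_lt(sil(pc_cor), sil(pc_raw))
})

test_that("PCA embedding has the expected spectral properties", {
  set.seed(3)
  x <- matrix(rnorm(50 * 20), 50, 20)
  p <- pca_embed(x, 5)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lte(sum(pca_embed(x, 5)$var_explained), 1)

  ## rank-1: two perfectly correlated genes -> PC1 explains everything
  y <- rbind(g1 = 1:10, g2 = 2 * (1:10))
  expect_equal(pca_embed(y, 1)$var_explained[1], 1)

  ## full-rank reconstruction recovers the input
  xs <- matrix(rnorm(12 * 6), 12, 6)
  pc <- prcomp(t(xs), center = TRUE)
  rec <- t(pc$x %*% t(pc$rotation)) + rowMeans(xs)
  expect_equal(rec, xs, ignore_attr = TRUE, tolerance = 1e-10)

  expect_error(pca_embed(matrix(1, 5, 5), 2), "variance")
})

test_that("BH adjustment matches the hand-executed step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)
  ## p * m / i followed by cumulative minima from the largest rank
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  ## manual step-up on an unsorted vector: sort, p * m / i, cumulative min
  ## from the largest rank, map back to the input order
  p <- c(0.2, 0.001, 0.9, 0.04, 0.01)
  o <- order(p)
  stepped <- p[o] * length(p) / seq_along(p)
  manual <- pmin(rev(cummin(rev(stepped))), 1)[order(o)]
  expect_equal(bh_adjust(p), manual)
})

test_that("de_test applies the DEG thresholds boundary-inclusively", {
  ## construct a result and check the flag rule directly on its columns
  sim <- simulate_counts(small_design())
  de <- de_test(sim$counts, sim$metadata$condition, reference = "nonOA")
  expect_true(all(de$is_deg ==
                    (abs(de$log2FC) >= log2(1.5) & de$padj <= 0.10)))
  expect_true(all(de$padj >= 0 & de$padj <= 1))
  ## fc 1.6 at padj 0.05 is a DEG; fc 1.4 at padj 0.01 is not
  expect_true(log2(1.6) >= log2(1.5) && 0.05 <= 0.10)
  expect_false(abs(log2(1.4)) >= log2(1.5))
})

test_that("de_test is well calibrated under the null and detects planted effects", {
  ## null: identical means in both arms -> small |lfc|, roughly uniform p
  d <- simulation_design(n_genes = 400, n_control = 25, n_groupA = 25,
                         n_groupB = 2, n_shared_de = 0, n_specificA = 0,
                         n_specificB = 0, dispersion = 0.05, n_batches = 1,
                         batch_lfc_sd = 0, seed = 31)
  sim <- simulate_counts(d)
  sel <- sim$metadata$condition == "nonOA" | sim$metadata$group %in% "A"
  de <- de_test(sim$counts[, sel], sim$metadata$condition[sel])
  expect_lt(median(abs(de$log2FC)), 0.2)
  expect_gt(mean(de$pvalue > 0.5), 0.35)   # roughly uniform p values

  ## planted 4-fold gene at n = 20 + 20 is called
  d2 <- simulation_design(n_genes = 200, n_control = 20, n_groupA = 20,
                          n_groupB = 2, n_shared_de = 0, n_specificA = 10,
                          n_specificB = 0, lfc_magnitude = 2,
                          dispersion = 0.05, n_batches = 1, batch_lfc_sd = 0,
                          seed = 32)
  sim2 <- simulate_counts(d2)
  sel2 <- sim2$metadata$condition == "nonOA" | sim2$metadata$group %in% "A"
  de2 <- de_test(sim2$counts[, sel2], sim2$metadata$condition[sel2],
                 reference = "nonOA")
  planted <- names(sim2$truth$de_genes_A)
  hits <- de2[match(planted, de2$gene), ]
  expect_true(all(hits$is_deg))
  ## estimated lfc close to the planted +-2
  expect_equal(hits$log2FC, unname(sim2$truth$de_genes_A), tolerance = 0.15)
})

test_that("de_test respects label symmetry and sample order", {
  sim <- simulate_counts(small_design(seed = 55))
  sel <- sim$metadata$condition == "nonOA" | sim$metadata$group %in% "A"
  counts <- sim$counts[, sel]
  cond <- sim$metadata$condition[sel]
  de_fwd <- de_test(counts, cond, reference = "nonOA")
  de_rev <- de_test(counts, cond, reference = "OA")
  expect_equal(de_fwd$log2FC, -de_rev$log2FC)
  expect_equal(de_fwd$pvalue, de_rev$pvalue)

  perm <- sample(ncol(counts))
  de_perm <- de_test(counts[, perm], cond[perm], reference = "nonOA")
  expect_equal(de_perm, de_fwd, ignore_attr = TRUE)
})

test_that("zero-count genes are excluded and reported, not an error", {
  m <- matrix(c(5L, 0L, 9L, 7L, 0L, 11L, 6L, 0L, 10L, 8L, 0L, 12L), 3, 4,
              dimnames = list(c("g1", "gz", "g2"), paste0("s", 1:4)))
  de <- de_test(m, c("x", "x", "y", "y"))
  expect_false("gz" %in% de$gene)
  expect_equal(attr(de, "excluded_genes"), "gz")
})

test_that("DEG set comparison partitions the union by membership", {
  mk <- function(genes, degs) {
    df <- data.frame(gene = genes, baseMean = 1, log2FC = 0, lfcSE = 1,
                     stat = 0, pvalue = 1, padj = 1,
                     is_deg = genes %in% degs, stringsAsFactors = FALSE)
    class(df) <- c("de_result", class(df))
    df
  }
  uni <- paste0("g", 1:10)
  ## identical DEG sets: everything shared
  same <- compare_deg_sets(mk(uni, c("g1", "g2")), mk(uni, c("g1", "g2")),
                           mk(uni, c("g1", "g2")))
  expect_equal(unname(same$summary[["distinctive_A"]]), 0)
  expect_equal(unname(same$summary[["shared_AB"]]), 2)

  ## disjoint toy sets
  cmp <- compare_deg_sets(mk(uni, character(0)), mk(uni, c("g1", "g2")),
                          mk(uni, "g3"))
  expect_equal(unname(cmp$summary[["distinctive_A"]]), 2)
  expect_equal(unname(cmp$summary[["distinctive_B"]]), 1)
  expect_equal(unname(cmp$summary[["shared_AB"]]), 0)
  expect_equal(sum(cmp$pattern$count), unname(cmp$summary[["union"]]))

  expect_error(compare_deg_sets(mk(uni, "g1"), mk(uni[-1], "g2"),
                                mk(uni, "g3")), "universe")
})

test_that("subgroup-specific DEG counts recover the planted partition", {
  d <- simulation_design(n_genes = 600, n_control = 15, n_groupA = 15,
                         n_groupB = 15, n_shared_de = 60, n_specificA = 40,
                         n_specificB = 30, lfc_magnitude = 2,
                         dispersion = 0.05, n_batches = 1, batch_lfc_sd = 0,
                         seed = 77)
  sim <- simulate_counts(d)
  md <- sim$metadata
  sub_de <- function(keep, ref) {
    de_test(sim$counts[, keep], md$condition[keep], reference = ref)
  }
  is_ctrl <- md$condition == "nonOA"
  de_all <- de_test(sim$counts, md$condition, reference = "nonOA")
  de_A <- sub_de(is_ctrl | md$group %in% "A", "nonOA")
  de_B <- sub_de(is_ctrl | md$group %in% "B", "nonOA")
  ## universes can differ by the all-zero filter; restrict to common genes
  common <- Reduce(intersect, list(de_all$gene, de_A$gene, de_B$gene))
  trim <- function(de) {
    out <- de[match(common, de$gene), ]
    class(out) <- class(de)
    out
  }
  cmp <- compare_deg_sets(trim(de_all), trim(de_A), trim(de_B))
  expect_equal(unname(cmp$summary[["distinctive_A"]]), d$n_specificA,
               tolerance = 0.25)
  expect_equal(unname(cmp$summary[["distinctive_B"]]), d$n_specificB,
               tolerance = 0.25)
})
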