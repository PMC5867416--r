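---
title: "Methods: stratifying osteoarthritis transcriptomes with oastrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratifying osteoarthritis transcriptomes with oastrat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical methods implemented in `oastrat`,
the parameter defaults and why they were chosen, the scope and limits of
the bundled simulator, and the judgement calls made where several
reasonable implementations exist.

## Problem setting

Bulk RNA-Seq of osteoarthritis (OA) cartilage shows more between-patient
heterogeneity than an OA-versus-control contrast explains. The pipeline
asks three questions of a count matrix plus sample metadata: (1) do the
patients split into reproducible molecular subgroups, (2) can a small gene
panel assign new patients to a subgroup, and (3) which pathways,
interaction subnetworks and secreted proteins distinguish the subgroups?

Because the real cohorts behind such analyses are not redistributable, the
package ships a simulator that plants all of the structure the pipeline is
supposed to find. Every acceptance claim is made against that known truth.

## Count model and differential expression

Counts are treated as negative binomial, `K ~ NB(mu, alpha)` with
`Var = mu + alpha mu^2`. Library depth is estimated by median-of-ratios
size factors: per gene, the ratio of each sample's count to the gene's
geometric mean; per sample, the median ratio over genes with nonzero
geometric mean. This is robust to the minority of genes that are truly
differential as long as most genes are not.

`de_test()` is a deliberately simple Wald test, not a GLM fit:

* group means on the common scale, `q_k = mean(K_gj / s_j)` within group k;
* a moment estimator of dispersion pooled within condition,
  `alpha = (var_pool - q * mean(1/s)) / q^2`, floored at `1e-8`;
* a lowess trend of `log(alpha)` on `log(q)` with shrinkage weight 0.3
  toward the trend, stabilising per-gene estimates at small n;
* delta-method standard error of `log2(q_A/q_B)` and a two-sided normal
  p value, Benjamini–Hochberg adjusted.

A gene is a DEG when `|log2 FC| >= log2(1.5)` **and** `padj <= 0.10`, both
boundaries inclusive. These thresholds are the package defaults
(`fc_min = 1.5`, `fdr_max = 0.10`) and are configurable. The acceptance
suite checks the operating characteristics that matter for the
stratification use case: on fully null simulations the mean
false-discovery proportion stays at or below 0.15 over 50 seeds, and
planted four-fold changes at 20 + 20 samples (dispersion 0.05) are
detected with power at least 0.95.

Batch correction is location-only: each gene's batch means are equalised
to its global mean. The simulator plants batch effects as additive shifts
in log space, and the claim tested is only that batch separation in PC
space decreases — not that arbitrary batch distortions are removed. For
real data with unbalanced designs a covariate-adjusted method should
replace this step.

## Stratification: network-regularised NMF plus consensus

The clustering input is the log-normalised, batch-corrected expression of
the OA samples only (controls are excluded from clustering but used for
differential expression), restricted to the `top_n = 2000` most variable
genes and shifted per gene to be non-negative.

`nmf_fit()` minimises

```
||X - WH||_F^2 + lambda * tr(W' L W)
```

by multiplicative updates, where `L = D - A` is the graph Laplacian of the
interaction network restricted to the clustered genes. With
`normalise_laplacian = TRUE` (default) the adjacency is degree-normalised,
`D^{-1/2} A D^{-1/2}`, and the degree term becomes an indicator of network
membership; this keeps the penalty per gene O(1) regardless of hubness and
makes `lambda` comparable across networks. At `lambda = 0` the updates are
exactly Lee–Seung NMF; the acceptance suite verifies bit-level agreement
with an independently written reference implementation and monotone
objective traces across 100 seeded runs.

Stochastic NMF runs are aggregated by consensus clustering
(`consensus_cluster()`): `n_runs = 500` runs, each on a random 80 % sample
subset, each sample labelled by its dominant factor (row of `H`), and each
sample pair scored by the fraction of co-sampled runs in which it was
co-labelled. The number of clusters is selected (`select_k()`) over
`k = 2..5` by the mean silhouette of the average-linkage cut of
`1 - coclustering`, ties toward smaller `k`. 500 runs and 80 % subsampling
follow common consensus-clustering practice: enough runs that co-clustering
fractions have Monte-Carlo error well below the signal, and subsampling so
the consensus reflects stability under cohort perturbation, not only
initialisation.

Patients whose silhouette in the final cut is below `min_silhouette = 0`
are reported as `unassigned`. Zero is the canonical boundary — a negative
silhouette means the patient is, on average, closer to another cluster
than to its own — and makes "excluded" a statement about the consensus
geometry rather than a tuned cutoff.

A note on what exclusion can and cannot see: a patient whose profile is a
clean 50/50 mixture of two subgroups flips cluster from run to run, but
two such patients tend to flip *together*, co-cluster with each other, and
end up with a small positive silhouette. Negative silhouettes arise when a
patient co-clusters moderately with a group without belonging to its core.
The exclusion acceptance test therefore constructs a consensus matrix with
exactly that geometry (via `consensus_from_matrix()`, the entry point for
externally computed ensembles) rather than pretending expression-level
mixtures would do it.

## Classifier panel

`nsc_statistics()` implements nearest shrunken centroids: standardised
class-centroid distances `d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s0))`
with pooled within-class `s_i`, fudge `s0 = median(s_i)` and
`m_k = sqrt(1/n_k - 1/n)`. Soft-thresholding by `delta` shrinks panels
monotonically; `select_panel_size()` exploits the resulting step function
to hit a target panel size exactly (default `panel_size = 10`).

`train_panel_classifier()` fits a linear soft-margin SVM (`cost = 1`, not
tuned inside the reporting CV, to avoid optimistic bias) on the panel,
with per-gene standardisation computed from training folds only. The
reported `cv_auc` is the rank-based (Mann–Whitney) AUC of held-out
decision scores pooled over `folds = 5` stratified folds — pooling is more
stable than per-fold AUC at cohort sizes of a few dozen. Score orientation
is fixed per fold using training data only. Under label permutation with
the panel held fixed, the CV AUC is centred at 0.5 (acceptance-tested over
50 seeds); note that re-selecting the panel on permuted labels using all
samples would instead produce optimistically biased AUCs — a selection
leak, not a property of the classifier.

## Pathways, subnetworks, biomarkers

`ora()` is the standard hypergeometric upper tail against a stated
universe (the DE-tested genes), BH-adjusted across sets; it matches
exhaustive enumeration on small universes.

`find_subnetworks()` scores connected subgraphs by
`sum(weight_g * |log2FC_g|) / sqrt(|S|)`, growing greedily from each local
maximum until no positive score gain or `max_subnetwork_size = 30`. Node
weights default to uniform; `rwr_weights()` provides
random-walk-with-restart weights from a seed-gene list (restart 0.5,
power iteration to an L1 residual of 1e-10, verified against the direct
linear solve). Near-duplicate subnetworks (Jaccard > 0.5) are collapsed.

The permutation null shuffles fold changes over nodes and records, per
permutation, the **best** greedily grown score under the same size cap as
the observed run. Each reported subnetwork is compared against this
permutation maximum. For the top-ranked subnetwork this compares a maximum
with a maximum, so its p value is exactly uniform under exchangeable fold
changes (acceptance: KS test over 200 seeded nulls); lower-ranked
subnetworks are conservative. The alternative — capping each null re-growth
at the observed subnetwork's own size — was measured to be conservative
even for the top hit (mean null p 0.59) because natural greedy stopping
sizes differ between observed and null draws, and was rejected for that
reason.

`secreted_biomarkers()` intersects the subgroup-contrast DEGs with a
secreted-protein list and reports the higher-expressing group and the
linear fold increase `2^|log2FC|` — the shape of a synovial-fluid
candidate table. Secreted genes never tested (absent from the DE universe)
are counted in an attribute rather than dropped silently.

## Simulator: scope and limits

`simulation_design()` defaults plant exactly the structure the pipeline
claims to recover: 10 controls plus OA subgroups of 24 and 18; 2000 genes;
300 DE genes shared by both subgroups and 150 + 150 subgroup-specific, all
at `|log2 FC| = 1`; gene-level dispersion 0.1; baseline means log-uniform
over 10^0.5..10^3.5; depth factors log-uniform in 0.5..2; two balanced
batches shifting a random 20 percent of genes by N(0, 0.5) in log2.
`simulate_network()` wires each planted DE set into a dense module
(density 0.1 by default) over a sparse background (expected degree 2) and
keeps the graph connected.

Limits worth knowing: dispersion is constant across genes (no mean–
dispersion trend), batch effects are additive in log space and balanced
across arms, fold changes are exact and common within a planted set, and
the network modules coincide exactly with the planted DE sets. The
simulator is a test harness for the pipeline's statistical claims, not a
generative model of cartilage biology.

## Reproducibility

All stochastic stages draw their seeds from one root seed through named
streams (`stage_seed()`), so stages can be re-run independently yet
reproducibly and the global RNG state never leaks in. `run_pipeline()`
writes a manifest with parameter values, stage seeds and MD5 checksums of
every input and output, and contains no timestamps: two runs from one
configuration are byte-identical, which is itself an acceptance criterion.

Problem sizes in the acceptance suite (e.g. 500 consensus runs over
`k = 2..5` on the default design, 1000 subnetwork permutations, 200-seed
null calibrations) were chosen as the largest sizes that keep the whole
suite within a few minutes on one CPU while leaving the tested claims at
their intended scale; `scripts/acceptance.R` recomputes the same
quantities from scratch against the installed package.
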