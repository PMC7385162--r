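---
title: "Repeated metaclustering: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeated metaclustering: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A mass cytometry (CyTOF) cohort measures tens of protein markers on
hundreds of thousands to millions of cells per blood sample, over tens
to hundreds of samples. The analytical goal this package addresses is
threefold: discover cell populations shared across all samples, use
their per-sample abundances to classify samples by a binary clinical
phenotype, and show *which* cells carry the class difference.

The standard route — cluster all cells once, compute per-cluster
frequencies, classify — has a known weakness: the clustering algorithms
used at this scale are stochastic, and different runs produce different
cell-to-cluster assignments, different engineered features, and visibly
different classification accuracies. Rather than trying to pick the
"best" single solution, `cytopool` embraces the variability: it
generates many independent metaclustering solutions and pools the
features engineered from all of them. Ensembling over solutions both
raises the expected accuracy and shrinks its variance, for the same
reason averaging any collection of diverse, individually noisy
predictors does.

## The procedure

1. **Within-sample clustering.** Every sample's cells are coarsely
   over-clustered with k-means (`k_per_sample`, default 1000). This is
   a data-reduction step, not population discovery: with far more
   clusters than true populations, each cluster is a small,
   homogeneous parcel of cells, and *every* cell of every sample is
   represented by some parcel — no downsampling anywhere in the
   modeling path. Clustering uses phenotypic *and* functional channels
   jointly, so parcels are coherent in both identity and signaling
   state.
2. **Repeated metaclustering.** The `K = sum(k_i)` parcel centers are
   pooled and re-clustered into `K'` metaclusters (default 50). This
   metaclustering step is repeated `I` times (default 50) with
   independent seeds; each run is one stochastic "view" of the
   population structure, giving `P = I * K'` overlapping metaclusters.
   The within-sample stage is computed once and shared across
   iterations — stochasticity enters at the metaclustering stage (a
   `recluster_each` flag re-runs both stages per iteration for users
   who want the more expensive variant).
3. **Frequency features.** `F[i, j]` is the proportion of sample `i`'s
   cells assigned to metacluster `j`. Because clustering saw functional
   channels, a frequency feature can encode, say, "CD4 T cells with
   high pSTAT5" — phenotype and function in one number. Within each
   iteration's block of `K'` columns every row sums to exactly 1.
   Functional mean-expression features (`S x (P * f)`) are available
   as an opt-in; frequencies alone are the default classification
   input.
4. **Unsupervised feature selection.** The `P` features are highly
   redundant. Inside each iteration's block independently, a
   k-nearest-neighbor graph over the samples is built from that block,
   and each column is ranked by its Laplacian score — a
   locality-preservation criterion (He et al.): features varying
   smoothly over the sample-similarity graph score low (good). The
   `top_m` (default 40 of 50) lowest-scoring columns are retained.
   Class labels are never an input, so selection cannot leak outcome
   information into cross-validation.
5. **Classification.** Patient-level bootstrapped leave-group-out CV:
   in each of `B` (default 500) iterations, a random half of the
   *patients* — all their samples move together — trains a random
   forest; held-out samples receive class-1 probabilities. Each
   sample's final prediction is the *median* probability over its test
   appearances, and AUROC of those medians is the headline metric.
6. **Differentiation scores.** For visualization, each metacluster gets
   a two-sided Wilcoxon rank-sum p-value `w_j` comparing its frequency
   between the two groups (optionally within a comparison subset, e.g.
   one timepoint). Each cell in a 30,000-cell subsample is scored per
   solution by the similarity-weighted average
   `p_i = sum_j s_ji w_j / sum_j s_ji` with
   `s_ji = exp(-alpha * ||c_j - x_i||)`, then averaged over the `I`
   solutions and painted onto a 2-D embedding. Low scores flag cells in
   outcome-associated populations.

## Parameters that matter

| parameter | default | meaning / why |
|---|---|---|
| arcsinh cofactor | 5 | community-standard CyTOF variance stabilization; per-channel override; required for Euclidean clustering to be meaningful |
| `k_per_sample` | 1000 | parcel resolution; only needs to be well above the plausible population count; capped at the sample's cell count |
| `k_prime` | 50 | population resolution per solution |
| `n_iterations` | 50 | ensemble size; accuracy variance shrinks roughly like 1/I |
| `k_nn` | 5 | sample-graph connectivity for the Laplacian score |
| bandwidth | squared median pairwise distance | heat-kernel scale; scale-free default; `kernel = "binary"` available |
| `top_m` | 40 | features kept per solution (80% of `k_prime`) |
| `B` | 500 | CV bootstrap iterations; an upper bound — iterations whose training half lacks a class are skipped and counted |
| `train_fraction` | 0.5 | patient split; `floor` of the patient count trains |
| `alpha` | 1 | similarity decay for differentiation scores, applied after per-channel standardization of cells and centers (similarity computation only), which makes 1 a scale-free choice |
| `n_cells` | 30000 | visualization subsample; modeling always uses all cells |

## Numerical and design choices

- **k-means details.** Both stages use k-means++ initialization with 10
  restarts, keeping the lowest within-cluster sum of squares; on tiny
  instances this provably reaches the exhaustive-enumeration optimum
  (tested). Empty clusters are dropped and relabeled, so `k` is an
  upper bound; centers are recomputed as exact member means. Any
  clusterer with the `(matrix, k, seed) -> assignments` contract can
  replace k-means in either stage.
- **Seeding.** One master seed drives everything through a
  counter-based child-seed scheme (stream × index mixing), so results
  are independent of execution order and two runs with the same config
  are byte-identical, artifact for artifact.
- **Metaclustering is unweighted.** Parcel centers enter metaclustering
  without size weights (sizes are kept as diagnostics). Weighting would
  let very large parcels dominate metacluster placement and would
  couple the two stages more tightly; unweighted centers keep the
  second stage a pure geometry-of-populations step.
- **Ties and degeneracies.** Laplacian-score ties break by ascending
  column index; a constant feature gets `+Inf` (never retained while
  informative ones remain). A constant prediction vector gives AUROC
  0.5 via midranks. Cells whose similarity to every center underflows
  fall back to the nearest center's `w`. An identical-multiset rank-sum
  comparison returns p = 1.
- **Wilcoxon flavor.** Exact p-values when both groups have ≤ 25
  samples (tie-free case), normal approximation with tie correction
  otherwise. The `w_j` are deliberately *not* multiplicity-corrected:
  they order cell populations for visualization and are not
  confirmatory statistics.
- **Empty functional cells.** A (sample, metacluster) pair with no
  cells has no defined functional mean; it is imputed with the
  column's cross-sample mean rather than a fabricated zero signal.
- **Embedding.** The 2-D embedding is fully pluggable (`tsne` via
  Rtsne by default, `pca2`, or any user function); the scores, not the
  embedding, carry the statistical content.
- **Config validation** is plain aggregated R checks (one error
  listing every problem), and every artifact directory carries a
  provenance JSON with the config hash, master seed and package
  version.

## What the synthetic generator does and does not emulate

`generate_cohort()` draws each sample's population proportions from a
Dirichlet centered on its class's target frequency vector
(concentration `kappa`, default 100 — about 20–25% coefficient of
variation for mid-frequency populations, typical of inter-sample immune
variation), then draws cells from diagonal Gaussian populations
directly on the post-arcsinh scale. Class effects are multiplicative
frequency shifts, renormalized to keep proportions summing to 1 (so a
planted effect also slightly shifts every other population — exactly as
a real expansion of one compartment would).

The default fixture is 5 populations over 10 channels (6 phenotypic, 4
functional), one population at base frequency 0.15 carrying a 1.5×
effect, 10 patients per class with one 2,000-cell sample each. At this
scale the full pipeline runs in seconds per seed; tests use
`k_per_sample = 50`, `k_prime = 10`, `n_iterations = 10`, keeping the
1000-cells-per-parcel-budget ratio of the production defaults.

Deliberately not simulated: batch effects, spillover, doublets,
acquisition drift, non-Gaussian population shapes, and functional-only
(frequency-null) effects. Passing tests therefore demonstrate that the
machinery recovers planted *abundance* differences under realistic
sampling noise — not that it is robust to every artifact of real
acquisitions.

Two null-behavior facts worth knowing before reading any AUC from small
cohorts:

- **Pessimistic CV bias.** With simple random patient halves (the
  default, matching the classical leave-group-out design), the training
  set's class composition anti-correlates with the held-out
  composition; the classifier's predictions inherit that, and on *null*
  data the median-aggregated AUROC lands systematically below 0.5 — the
  effect grows with feature dimension (in our measurements, mean null
  AUC ≈ 0.48 with 5 features but ≈ 0.30 with 80 features at 40
  samples). This is the small-sample CV bias long documented in the
  classification-error-estimation literature, not information leakage:
  the companion check that the metacluster p-values `w_j` stay
  uniform-like under the null passes cleanly. `run_cv(stratified =
  TRUE)` draws training patients per class and recenters the null at
  0.5 (logged when used); it is off by default to keep the classical
  design, and is the recommended setting for null controls and
  imbalanced cohorts.
- **Per-draw spread.** A single random labeling of a few dozen samples
  can be genuinely (anti-)predictable; per-seed null AUCs spread with
  sd ≈ 0.1, so null checks should average over seeds or permutations
  rather than trust one draw.

And one power fact about recovery experiments: with 10 patients per
class and ~24% inter-sample frequency variation, a 1.5× abundance shift
on a 15%-frequency population is the strongest class difference in the
ground-truth sample frequencies in only ~19 of 20 cohort draws, and the
pipeline's minimum-p metacluster identifies it in ~16 of 20 — the
remainder lost to rank-sum multiplicity across the ~100 overlapping
metacluster features and to a parcel-count quantization artifact
(samples devote parcels to a population in proportion to its abundance,
which can class-correlate the sub-splitting of *null* populations).
Cohorts of this size support population discovery and ranking, not
guaranteed top-1 identification.

## Limitations

- Metaclusters are unlabeled; mapping them to named cell types remains
  an expert step (median marker expression per metacluster is
  available for that purpose).
- The redundancy that selection removes is of the uninformative kind:
  exact duplicates of *informative* features score identically well
  and are retained together — the Laplacian score ranks features
  individually and has no notion of mutual redundancy. Two further
  caveats measured on synthetic cohorts: the score is computed on a
  graph built from the very block it must clean, so when junk columns
  contribute a large share of the block's variance they corrupt the
  graph and partially protect themselves; and at desk scale (tens of
  samples, ~150 features) a random forest is largely insensitive to a
  modest junk fraction, so selection's AUC effect is ≈ 0 there — its
  measurable classification benefit belongs to cohort/feature scales
  an order of magnitude larger.
- Adding new samples requires re-running metaclustering; there is no
  incremental update.
- Binary endpoints only; the feature matrix itself is
  endpoint-agnostic and can be reused with other models.
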