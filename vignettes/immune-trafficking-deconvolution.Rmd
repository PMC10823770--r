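---
title: "Immune-cell deconvolution and trafficking stratification: methods"
author: "decontox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune-cell deconvolution and trafficking stratification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decontox)
```

## The problem

Toxicogenomics databases record bulk liver transcriptomes of rats treated
with hepatotoxic compounds at several doses and times, but carry no direct
information about the immune cells infiltrating or leaving the tissue.
Reference-based deconvolution recovers that layer: given expression
profiles of purified immune-cell populations, the composition of a bulk
sample can be estimated from the genes that mark each population, and the
time course of those estimates — immune-cell trafficking — becomes a new,
interpretable feature space in which compounds can be compared and
stratified.

`decontox` implements that pipeline for a six-population immune panel
(neutrophils, monocytes, CD4 T cells, CD8 T cells, NK cells, B cells):
signature construction, penalized regression estimation, control-matched
z-scoring, ensemble embedding with spectral meta-combination, hierarchical
stratification, and gene-set characterization of the resulting clusters.
A synthetic-data generator emulates the whole study design so each stage
is testable against a known ground truth.

## Signature construction

Reference profiles are collapsed to one column per cell type (arithmetic
mean over sorted-cell replicates), mapped to gene symbols with per-sample
medians over duplicate identifiers, and intersected with the bulk matrix's
genes. A gene qualifies as a marker of type $k$ when its pseudocounted
expression exceeds 1.5-fold that of *every* other type:

$$\frac{x_{gk} + c}{\max_{j \ne k}\, x_{gj} + c} > 1.5, \qquad c = 1,$$

and up to 200 qualifying genes per type are kept, ranked by that ratio.
Requiring enrichment against all other types makes the marker lists
disjoint by construction. The pseudocount stabilizes zero denominators in
linear-scale data; with $c = 0$ the rule is exactly scale invariant, and
the package tests assert that invariance. Fold changes are evaluated on
linear-scale values; depleted genes (ratio < 1/1.5) are deliberately not
treated as markers — a signature is built from genes *enriched* in a
population, and a depletion signal is not attributable to any single type.
Ties in the ranking are broken lexicographically by gene id so the
signature is deterministic.

## Score estimation

With the signature $X \in \mathbb{R}^{N \times K}$ (marker genes by cell
types) and a bulk sample $y \in \mathbb{R}^N$, scores solve the elastic
net

$$\hat p = \arg\min_p \; \lVert y - Xp \rVert_2^2
  + \lambda \left[ \tfrac{1-\alpha}{2} \lVert p \rVert_2^2
  + \alpha \lVert p \rVert_1 \right],
  \qquad \lambda = 1, \; \alpha = 0.05,$$

independently per sample, by coordinate descent on exactly this objective.
Two points deserve emphasis:

* **No $1/(2n)$ factor.** Popular library parametrizations divide the data
  term by $2n$; the package's solver minimizes the un-normalized objective
  above. The unit test that cross-checks against `glmnet` rescales the
  penalty ($\lambda_{\text{glmnet}} = \lambda/(2n)$, no standardization,
  no intercept) and additionally verifies the $\alpha = 0$ limit against
  the ridge closed form $(X^\top X + \tfrac{\lambda}{2} I)^{-1} X^\top y$,
  which follows directly from differentiating the objective.
* **No intercept, no predictor standardization, no simplex constraint.**
  The objective contains none of these; all are exposed as configuration
  flags (`fit_intercept`, `nonneg_clip`) for sensitivity analysis.
  Estimates are unconstrained scores, not proportions — every downstream
  use works on z-scored values, for which a sum-to-one renormalization
  would be immaterial.

An independent proximal-gradient reference solver
(`enet_prox_reference()`) for the same objective serves as a numerical
oracle: on random instances the coordinate-descent objective agrees with
it to within $10^{-4}$ relative, and beats thousands of random candidate
solutions.

Convergence is declared when the largest coordinate update in a sweep
falls below `tol` ($10^{-6}$ by default; precision-critical checks in the
test suite tighten it to $10^{-10}$–$10^{-12}$, which costs little at
$K = 6$).

## Z-score conventions

Two distinct normalizations are used, matching their distinct purposes:

* `zscore_vs_control()` — each treated value is expressed in SD units of
  its matched vehicle-control group (same `control_group_key`, typically
  the same time point), $z = (v - \bar v_{\text{ctrl}}) / s_{\text{ctrl}}$
  with the sample SD ($n-1$ denominator). Controls are transformed with
  their own group statistics, so every transformed control block has
  per-feature mean zero (asserted to $10^{-12}$). Groups need at least two
  controls; a zero control SD is an error, never silently patched.
* `zscore_between_samples()` — features are standardized across the
  compared samples before concordance analysis. Pearson correlation is
  affine invariant, so this step cannot change $r$; the package asserts
  that numerically rather than assuming it.

The $n-1$ denominator was chosen over $n$; with the control-group sizes
involved the difference is immaterial, but a single convention is applied
everywhere.

## Trafficking features and ensemble stratification

Compounds passing the ALT filter (peak ALT $\ge 65$ IU/l across treated
samples within 24 h — the maximum over doses is used, since any dose
reaching the threshold marks the compound as hepatotoxic) are described by
16 features: the control-z-scored estimates of the four reliably estimated
populations (monocytes, neutrophils, CD4 T, CD8 T) at 3, 6, 9 and 24 h,
averaged over replicates (the mean, not the median: features are already
z-scores and replicate counts are small).

Six 2-D candidate embeddings of the feature table are built: locally
linear embedding, metric MDS, spectral embedding, PCA, t-SNE and UMAP.
MDS and PCA come from `stats`, t-SNE from `Rtsne`, UMAP from `uwot`; LLE
and spectral embedding are implemented in the package (standard
algorithms; no installed R package provides them). At $n = 16$ compounds
the methods run with small-$n$ safeguards — t-SNE perplexity
$\min(5, \lfloor (n-1)/3 \rfloor)$, neighbour counts $\min(15, n-1)$, LLE
neighbours $\min(5, n-2)$ — and any method that still cannot run is
dropped with a warning rather than failing the ensemble.

### Spectral meta-combination

For each compound $i$, its vector of distances to the other compounds in
candidate $k$ is normalized to unit length; the $K \times K$ matrix of
inner products of these normalized vectors measures local agreement
between candidates, and the absolute entries of its leading eigenvector
(renormalized to sum 1; uniform weights on a tied leading eigenvalue) give
per-candidate weights. The meta-distance row for $i$ is the weighted sum
of candidate distances, and the matrix is symmetrized with an exactly zero
diagonal.

One design choice departs from the straightforward "combine the
unit-normalized vectors" reading: in the combination step each candidate
is scaled by a single global factor (the Frobenius norm of its full
distance matrix) rather than per-row norms. Per-row scaling followed by
the required symmetrization multiplies $d_{ij}$ by
$(1/\lVert d_i \rVert + 1/\lVert d_j \rVert)/2$, which is not
rank-preserving even when all candidates are identical — it would break
the basic sanity property that duplicated candidates return their common
distance structure unchanged. With one global scale per candidate the
combination is exactly proportional to the common distance matrix in that
case (weights $1/K$ each), while candidates with arbitrary coordinate
scales remain commensurable. The per-point weights are unaffected: they
are still computed from the unit-normalized vectors.

The meta-distance is clustered by average-linkage agglomeration
(`hclust` on the precomputed dissimilarity; Ward linkage is not
meaningful here because the meta-distance is not Euclidean), cut at 4
clusters, and labels are renumbered deterministically (increasing cluster
size, ties by lexicographically first member). A 2-D consensus layout via
metric MDS of the meta-distance is provided for plotting only.

Per-cluster time courses report the mean with a normal-approximation 95%
CI ($\pm 1.96\,\mathrm{SE}$); a cell with a single sample reports its mean
with the CI flagged undefined instead of a fabricated interval.

## ssGSEA and discriminative terms

The enrichment score of sample $v$ for set $S$ ranks all $N$ genes by
expression, descending (ties broken by gene id); position $i$ carries rank
value $r_i = N - i + 1$ and, for set genes, weight $w_i = r_i^\tau$ with
$\tau = 0.75$. The score is

$$ES = \sum_{i=1}^{N} \left[ \frac{\sum_{j \le i,\, j \in S} w_j}
 {\sum_{j \in S} w_j} - \frac{\#\{j \le i,\, j \notin S\}}{N - |S|} \right],$$

optionally divided by $N$ (`normalize = TRUE`, the default; both variants
are available because published ssGSEA implementations disagree on this
point). The score is purely rank-based, hence invariant under monotone
transforms — asserted in tests, along with exact agreement of the
$\tau = 0$ case with a brute-force cumulative-fraction oracle and a
hand-derived 4-gene worked example ($ES = 2$ for a single top-ranked set
gene at $\tau = 1$, unnormalized).

Cluster-discriminative sets are found by a two-sided Mann-Whitney U test
of each set's scores in one cluster's samples against all others, with
Bonferroni correction across sets within each cluster contrast. The test
and correction are deliberately conservative defaults for small,
non-normal score samples; a $t$-test and other `p.adjust` methods are
available by argument. Direction is the sign of the median difference.

## The synthetic-data generator

`simulate_study()` emulates the structure of a compound-treatment liver
time course: 16 compounds assigned round-robin to 4 trafficking clusters,
times 3/6/9/24 h, 3 replicates per condition, matched vehicle controls,
per-sample ALT, and baseline hematology analytes. Bulk mixtures follow
the generative counterpart of the deconvolution model, $Y = XP$ with
multiplicative log-normal noise (log-SD 0.1 by default), from a reference
of 2000 genes with 100 planted markers per type at fold change 5 —
the same conditions under which estimation accuracy is tested.

Choices that matter, and why:

* **Control baseline** is neutrophil-skewed
  (0.35/0.20/0.15/0.12/0.10/0.08) rather than uniform, so control
  z-scoring is exercised against a non-trivial composition.
* **Biological variability** of control proportions (`prop_sd = 0.04`,
  i.e. ~11% CV on the neutrophil fraction) is deliberately set to dominate
  the deconvolution measurement error (~0.015–0.02 on the same scale).
  This mirrors real bulk cohorts, where between-animal variation exceeds
  estimation noise for well-estimated populations; if the two were
  comparable, the control SD in the z-score denominator would largely
  measure noise and the effect-size unit would lose its meaning.
* **Effect sizes** are expressed in control-SD units: cluster archetypes
  are (cell type × time) patterns with unit peak amplitude, scaled by
  `effect_scale` × `prop_sd` and added to the baseline before
  renormalization to the simplex. The four archetypes (early neutrophil
  influx, mid monocyte accumulation, late T-cell rise, neutrophil efflux
  with early CD8) are built to be strongly mutually distinct, because they
  define planted structure the pipeline is supposed to recover — a
  generator whose classes overlap by construction cannot certify
  anything.
* **Controls are pooled per time** (10 vehicle samples), as when matched
  controls of the same design are pooled across studies; small control
  groups make the SD estimate in the z-score denominator unstable enough
  to scramble whole feature columns.
* **ALT** is drawn at 100–300 IU/l for treated samples and 20–40 for
  controls, so the ALT ≥ 65 filter retains every treated compound even in
  the null (`effect_scale = 0`) study — clustering robustness can then be
  probed separately from the filter.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: dose-response structure (one dose group),
probe-level microarray artefacts and batch effects, correlated marker
expression between related cell types (each gene marks exactly one type),
liver-resident subpopulations with profiles diverging from circulating
cells (the reason NK and B estimates validate poorly in practice), blood
contamination of liver tissue, and missing or unbalanced designs. Recovery
rates measured here are upper bounds on what equally sized real studies
would give.

## Problem sizes and runtime envelope

The test suite and the acceptance analysis use: 20 random instances
(50 genes × 6 types) for solver-oracle equivalence; 30 Dirichlet(1)
mixtures over a 2000-gene reference for noisy recovery; 20 generator seeds
at `effect_scale = 3` plus 10 seeds at each of 1.5, 0.75 and 0 for
planted-cluster recovery (the full pipeline runs in ~2 s per study, so
the whole grid stays within a few minutes); 100 random instances for the
$\tau = 0$ ssGSEA oracle; and 200 gene sets (one planted) for term
discovery, scored on the 48 treated samples at the planted cluster's
peak-effect time. These sizes were chosen as the smallest at which the
measured quantities are stable across seeds.

## Known limitations

* Scores are unconstrained; strongly collinear signatures (closely related
  cell types) will show the usual instability of linear deconvolution, and
  nothing here enforces non-negativity unless `nonneg_clip` is set.
* The marker rule assumes one profile per type after replicate collapse;
  within-type heterogeneity is averaged away.
* The meta-visualization weights are per-point spectral weights over as
  few as 6 candidates; with very small $n$ the stochastic candidates
  (t-SNE, UMAP) contribute layouts whose fine structure is
  seed-dependent, which is why every entry point takes and logs a seed.
* Bonferroni across 200 sets is conservative by design; genuinely
  correlated sets (shared genes) make it more so.
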