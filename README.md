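# decontox

Reference-based immune-cell deconvolution of bulk liver transcriptomes and
stratification of hepatotoxic compounds by the immune-cell trafficking it
reveals.

Toxicogenomics databases hold time-course liver transcriptomes of rats
treated with hundreds of compounds, but no direct readout of the immune
cells entering or leaving the tissue. `decontox` recovers that layer for a
six-population panel (neutrophils, monocytes, CD4 T, CD8 T, NK, B cells)
and uses it to group compounds by the kinetics of their immune response,
with a synthetic-data generator that emulates the full study design so
every stage is testable against known ground truth.

## The model

Given a signature matrix `X` (N marker genes × K cell types, built from
sorted-cell reference profiles by keeping up to 200 genes per type whose
pseudocounted expression exceeds 1.5-fold that of every other type), each
bulk sample `y` yields cell-type scores by elastic-net regression

    p̂ = argmin_p ‖y − Xp‖₂² + λ[(1−α)/2 ‖p‖₂² + α‖p‖₁],   λ = 1, α = 0.05,

solved per sample by coordinate descent on exactly this objective (no
1/(2n) factor, no intercept, no standardization). Scores are z-scored
against matched vehicle controls; compounds passing an ALT ≥ 65 IU/l
filter are described by 16 trafficking features (4 cell types × 4 time
points), embedded by six methods (LLE, MDS, spectral, PCA, t-SNE, UMAP),
combined into a spectral meta-distance with per-point candidate weights,
and hierarchically clustered (average linkage). Clusters are characterized
by rank-weighted ssGSEA scores (exponent τ = 0.75) and Mann–Whitney tests
with Bonferroni correction. The methods vignette
(`vignettes/immune-trafficking-deconvolution.Rmd`) derives and motivates
every step.

## Worked example

The `analysis/` scripts run the whole pipeline on a simulated 16-compound
study and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # study + gene sets
Rscript analysis/02_signature.R    # marker selection, signature matrix
Rscript analysis/03_deconvolve.R   # elastic-net scores + control z-scores
Rscript analysis/04_stratify.R     # features, embeddings, meta-distance, clusters
Rscript analysis/05_enrichment.R   # ssGSEA + discriminative terms
```

Output of the run shipped with this repository's defaults (seed 2026):

```
study: 2000 genes x 232 samples (16 compounds, 10 controls/time)
signature: 600 marker genes x 6 cell types
  cell_type     r
1       Neu 0.956
2       Mon 0.973
3      CD4T 0.955
4      CD8T 0.968
5        NK 0.958
6         B 0.937
ALT filter (>= 65 IU/l within 24 h): 16/16 compounds retained
cluster sizes: 4/4/4/4
adjusted Rand index vs planted clusters: 1.000
planted set 'planted_01': best adjusted p = 0.000649 in cluster 1 (rank 1)
```

Reading: the per-cell-type Pearson `r` compares elastic-net scores with
the generator's true proportions across all 232 samples (≥ 0.94
throughout); the 16 compounds fall back into their 4 planted trafficking
clusters exactly (ARI 1.0); and the one gene set planted to track cluster
1's neutrophil influx surfaces as that cluster's top discriminative term.

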