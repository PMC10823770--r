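#' Run the trafficking stratification pipeline on a simulated study
#'
#' End-to-end driver used by the analysis scripts and the acceptance
#' checks: builds the signature from the study's reference profiles, fits
#' elastic-net cell scores on the bulk mixtures, z-scores them against the
#' matched controls, filters compounds by ALT, assembles trafficking
#' features, builds the embedding ensemble, combines it into the
#' meta-distance, and clusters the compounds.
#'
#' @param study Output of [simulate_study()] (or a list with the same
#'   `expression` / `meta` / `reference` elements).
#' @param cfg Elastic-net configuration (default [enet_config()]).
#' @param n_clusters Clusters to cut (default 4).
#' @param seed Seed for the stochastic embeddings.
#' @param fc_threshold,max_genes Marker-selection parameters.
#' @return List: `signature`, `scores` (raw), `z` (z-scored vs controls),
#'   `compounds` (ALT survivors), `features`, `embeddings`, `meta_distance`,
#'   `clusters`.
#' @export
run_trafficking_pipeline <- function(study, cfg = enet_config(), n_clusters = 4,
                                     seed = 0, fc_threshold = 1.5, max_genes = 200) {
  ref <- collapse_replicates(
    study$reference$reference,
    stats::setNames(study$reference$truth$cell_type_of_sample,
                    colnames(study$reference$reference)))
  both <- intersect_genes(ref, study$expression)
  markers <- select_markers(both$ref, fc_threshold = fc_threshold, max_genes = max_genes)
  X <- build_signature(both$ref, markers)
  Y <- both$mixture[rownames(X), , drop = FALSE]
  scores <- fit_proportions(Y, X, cfg)
  z <- zscore_vs_control(scores, study$meta)
  compounds <- filter_compounds_by_alt(study$meta)
  feats <- assemble_trafficking_features(z, study$meta, compounds = compounds)
  emb <- embed_candidates(feats, seed = seed)
  md <- meta_combine(emb)
  cl <- hierarchical_cluster(md, n_clusters = n_clusters)
  list(signature = X, markers = markers, scores = scores, z = z,
       compounds = compounds, features = feats, embeddings = emb,
       meta_distance = md, clusters = cl)
}
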