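#' @keywords internal
.default_cell_types <- function(k) {
  if (k == 6L) c("Neu", "Mon", "CD4T", "CD8T", "NK", "B") else paste0("CT", seq_len(k))
}

#' Simulate sorted-cell reference profiles with planted marker genes
#'
#' Baseline expression per gene is drawn log-normal (meanlog 3, sdlog 1),
#' shared across cell types; each planted marker gene is multiplied by
#' `marker_fc` in its target cell type only, then multiplicative log-normal
#' noise with log-sd `noise_sd` is applied. Marker lists are disjoint across
#' cell types. With `noise_sd = 0` every marker's target/other expression
#' ratio equals `marker_fc` exactly.
#'
#' @param n_cell_types Number of cell types (6 gives the immune panel
#'   Neu/Mon/CD4T/CD8T/NK/B).
#' @param n_genes Total genes; must be >= `n_cell_types * markers_per_type`.
#' @param markers_per_type Planted markers per cell type.
#' @param marker_fc Marker enrichment fold change (> 1).
#' @param noise_sd Log-sd of multiplicative noise (0 = noiseless).
#' @param seed Integer seed; identical seeds give identical output.
#' @param n_replicates Replicate columns per cell type (default 1; with
#'   replicates, columns are named `<type>_r<j>` and the truth records the
#'   sample -> cell type labeling).
#' @return List with `reference` (genes x columns matrix) and `truth`
#'   (list with `markers` per type, `cell_types`, `cell_type_of_sample`).
#' @export
simulate_reference <- function(n_cell_types = 6, n_genes = 2000,
                               markers_per_type = 100, marker_fc = 5,
                               noise_sd = 0, seed = 1, n_replicates = 1) {
  if (marker_fc <= 1) stop("marker_fc must be > 1: markers must be enriched")
  if (markers_per_type * n_cell_types > n_genes) {
    stop("markers_per_type * n_cell_types exceeds n_genes")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  types <- .default_cell_types(n_cell_types)
  baseline <- stats::rlnorm(n_genes, meanlog = 3, sdlog = 1)
  marker_pool <- sample(genes, markers_per_type * n_cell_types)
  markers <- split(marker_pool, rep(types, each = markers_per_type))[types]
  cols <- as.vector(t(outer(types, seq_len(n_replicates),
                            function(a, b) if (n_replicates == 1L) a else paste0(a, "_r", b))))
  ref <- matrix(baseline, nrow = n_genes, ncol = length(cols),
                dimnames = list(genes, cols))
  type_of <- rep(types, each = n_replicates)
  names(type_of) <- cols
  for (k in types) {
    idx <- match(markers[[k]], genes)
    ref[idx, type_of == k] <- ref[idx, type_of == k] * marker_fc
  }
  if (noise_sd > 0) {
    ref <- ref * exp(matrix(stats::rnorm(length(ref), 0, noise_sd), nrow = n_genes))
  }
  list(reference = ref,
       truth = list(markers = markers, cell_types = types,
                    cell_type_of_sample = type_of))
}

#' Simulate bulk mixtures from reference profiles and known proportions
#'
#' Forward model: `Y = X P`, one column per sample, followed by
#' multiplicative log-normal noise with log-sd `noise_sd`. With
#' `noise_sd = 0` the product is exact, so unregularized fitting recovers
#' `P` to numerical precision.
#'
#' @param reference Genes x cell-types matrix (one profile per type).
#' @param proportions Cell-types x samples matrix; columns non-negative
#'   and summing to 1.
#' @param noise_sd Log-sd of multiplicative noise.
#' @param seed Integer seed.
#' @return Genes x samples mixture matrix.
#' @export
simulate_mixture <- function(reference, proportions, noise_sd = 0, seed = 1) {
  stopifnot(is.matrix(reference), is.matrix(proportions))
  if (!identical(colnames(reference), rownames(proportions))) {
    stop("cell types of reference columns and proportion rows do not match")
  }
  if (any(proportions < 0)) stop("proportions must be non-negative")
  csum <- colSums(proportions)
  if (any(abs(csum - 1) > 1e-8)) stop("proportion columns must sum to 1")
  set.seed(seed)
  y <- reference %*% proportions
  if (noise_sd > 0) {
    y <- y * exp(matrix(stats::rnorm(length(y), 0, noise_sd), nrow = nrow(y)))
  }
  y
}

# Trafficking archetypes: per-cluster (cell type x time) effect patterns on
# the 4 accurately estimated cell types, in control-SD units before scaling.
# The four shapes (early-neutrophil influx, mid monocyte accumulation, late
# T-cell rise, neutrophil efflux with early CD8) are chosen to be strongly
# mutually distinct so the planted partition is the dominant structure of
# the feature table once effect_scale clears the replicate noise.
.archetypes <- function(times_h) {
  tt <- as.character(times_h)
  a <- list()
  mk <- function(...) {
    m <- rbind(...)
    dimnames(m) <- list(c("Neu", "Mon", "CD4T", "CD8T"), tt)
    m
  }
  nt <- length(times_h)
  ramp_up <- seq(0.2, 1, length.out = nt)
  ramp_dn <- rev(ramp_up)
  bump <- stats::dnorm(seq(-1.5, 1.5, length.out = nt)); bump <- bump / max(bump)
  a[[1L]] <- mk(pmin(ramp_dn * 1.4, 1), rep(0, nt), rep(0, nt), rep(0, nt))  # early Neu influx
  a[[2L]] <- mk(rep(0, nt), bump, rep(0, nt), rep(0, nt))                    # mid Mon accumulation
  a[[3L]] <- mk(rep(0, nt), rep(0, nt), ramp_up, ramp_up)                    # late T-cell rise
  a[[4L]] <- mk(rep(-0.7, nt), rep(0, nt), rep(0, nt), pmin(ramp_dn * 1.4, 1))  # Neu efflux / early CD8
  a
}

#' Simulate a multi-compound, multi-time-point toxicogenomics study
#'
#' Emulates a compound-treated liver time course with matched vehicle
#' controls: compounds are assigned round-robin to trafficking clusters; each
#' cluster has a distinct (cell type x time) trafficking archetype whose
#' amplitude is `effect_scale` in units of the control proportion SD;
#' per-sample true proportions are the control baseline plus the archetype
#' effect (clipped at 0, renormalized to the simplex) plus replicate-level
#' jitter; bulk mixtures come from [simulate_mixture()]; ALT is drawn high
#' (100-300 IU/l) for all treated samples and low (20-40) for controls,
#' hematology analytes are baseline noise.
#'
#' The control baseline is neutrophil-skewed rather than uniform so that
#' z-scoring against controls is exercised on a non-trivial baseline.
#'
#' @param n_compounds Number of treated compounds.
#' @param n_clusters Planted trafficking clusters (<= `n_compounds`,
#'   at most 4 distinct archetypes).
#' @param times_h Sampling times in hours after administration.
#' @param n_replicates Replicates per (compound, time) and per control group.
#' @param effect_scale Archetype amplitude in control-SD units (>= 0;
#'   0 = null study).
#' @param noise_sd Log-sd of multiplicative mixture noise.
#' @param seed Integer seed.
#' @param reference Optional precomputed output of [simulate_reference()];
#'   generated with the study seed when omitted.
#' @return List with `expression` (genes x samples), `meta` (sample metadata
#'   data.frame), `truth` (true proportions, markers, cluster labels, effect
#'   profiles) and `reference`.
#' @export
simulate_study <- function(n_compounds = 16, n_clusters = 4,
                           times_h = c(3, 6, 9, 24), n_replicates = 3,
                           effect_scale = 3, noise_sd = 0.1, seed = 1,
                           reference = NULL) {
  if (n_clusters > n_compounds) stop("n_clusters must be <= n_compounds")
  if (n_clusters > 4L) stop("at most 4 distinct trafficking archetypes are defined")
  if (effect_scale < 0) stop("effect_scale must be >= 0")
  set.seed(seed)
  if (is.null(reference)) {
    reference <- simulate_reference(seed = seed + 1000L)
  }
  ref <- reference$reference
  types <- reference$truth$cell_types
  stopifnot(all(c("Neu", "Mon", "CD4T", "CD8T") %in% types))

  compounds <- sprintf("cmp%02d", seq_len(n_compounds))
  cluster_of <- stats::setNames(rep(seq_len(n_clusters), length.out = n_compounds),
                                compounds)
  arch <- .archetypes(times_h)

  # neutrophil-heavy control baseline on the simplex; sd of replicate-level
  # proportion jitter defines the control-SD unit of effect_scale
  baseline <- stats::setNames(rep(0.02, length(types)), types)
  baseline[c("Neu", "Mon", "CD4T", "CD8T", "NK", "B")[seq_len(min(6, length(types)))]] <-
    c(0.35, 0.20, 0.15, 0.12, 0.10, 0.08)[seq_len(min(6, length(types)))]
  baseline <- baseline / sum(baseline)
  # between-animal biological variability of the control proportions; set so
  # it dominates the deconvolution measurement error (else control z-score
  # denominators would measure estimation noise rather than biology)
  prop_sd <- 0.04

  sample_ids <- character(0)
  meta_rows <- list()
  props <- list()
  add_sample <- function(id, compound, time, rep_i, is_ctrl, key, p) {
    sample_ids <<- c(sample_ids, id)
    meta_rows[[id]] <<- data.frame(
      sample_id = id, compound = compound, dose_group = if (is_ctrl) "vehicle" else "high",
      time_h = time, replicate = rep_i, is_control = is_ctrl,
      control_group_key = key, stringsAsFactors = FALSE)
    props[[id]] <<- p
  }

  jitter_p <- function(p) {
    q <- pmax(p + stats::rnorm(length(p), 0, prop_sd), 1e-4)
    q / sum(q)
  }

  # controls are shared per time across compounds (a pooled vehicle arm, as
  # when matched controls of the same design are pooled across studies), so
  # the control group is larger than a per-compound replicate set and the
  # control SD estimate in the z-score denominator is stable
  n_control <- max(10L, n_replicates)
  for (t in times_h) {
    key <- sprintf("ctrl_t%g", t)
    for (r in seq_len(n_control)) {
      add_sample(sprintf("%s_r%d", key, r), "vehicle", t, r, TRUE, key, jitter_p(baseline))
    }
  }
  for (cmp in compounds) {
    cl <- cluster_of[[cmp]]
    for (ti in seq_along(times_h)) {
      t <- times_h[ti]
      key <- sprintf("ctrl_t%g", t)
      target <- baseline
      eff <- arch[[cl]][, ti] * effect_scale * prop_sd
      target[names(eff)] <- target[names(eff)] + eff
      target <- pmax(target, 1e-4)
      target <- target / sum(target)
      for (r in seq_len(n_replicates)) {
        add_sample(sprintf("%s_t%g_r%d", cmp, t, r), cmp, t, r, FALSE, key, jitter_p(target))
      }
    }
  }

  P <- do.call(cbind, props)
  rownames(P) <- types
  colnames(P) <- sample_ids
  expr <- simulate_mixture(ref, P, noise_sd = noise_sd, seed = seed + 2000L)

  meta <- do.call(rbind, meta_rows)
  rownames(meta) <- NULL
  meta$alt <- ifelse(meta$is_control,
                     stats::runif(nrow(meta), 20, 40),
                     stats::runif(nrow(meta), 100, 300))
  for (an in c("total_bilirubin", "platelets", "red_blood_cells", "lymphocytes")) {
    meta[[paste0("hema_", an)]] <- stats::rnorm(nrow(meta), 100, 10)
  }
  validate_metadata(meta)

  effect_profiles <- lapply(seq_len(n_clusters), function(cl) arch[[cl]] * effect_scale)
  names(effect_profiles) <- as.character(seq_len(n_clusters))

  list(expression = expr, meta = meta,
       truth = list(true_proportions = P, true_markers = reference$truth$markers,
                    true_cluster = cluster_of, effect_profiles = effect_profiles,
                    baseline = baseline, prop_sd = prop_sd),
       reference = reference)
}

#' Simulate a gene-set collection with planted cluster-discriminative sets
#'
#' Discriminative sets are drawn from genes whose simulated expression is
#' shifted in the target cluster's compounds: the marker genes of the cell
#' type the cluster's trafficking archetype moves most. The remaining sets
#' are uniform random draws from the study's gene universe.
#'
#' @param study Output of [simulate_study()].
#' @param n_sets Total number of gene sets.
#' @param set_size Genes per set.
#' @param n_discriminative Number of planted discriminative sets
#'   (0 = all random).
#' @param target_cluster Planted cluster label the discriminative sets track.
#' @param seed Integer seed.
#' @return Named list of gene sets (GMT-compatible); planted set names start
#'   with `"planted_"`, the `"planted"` attribute lists them.
#' @export
simulate_gene_sets <- function(study, n_sets = 200, set_size = 25,
                               n_discriminative = 1, target_cluster = 1,
                               seed = 1) {
  universe <- rownames(study$expression)
  if (set_size > length(universe)) stop("set_size exceeds the gene universe")
  set.seed(seed)
  sets <- list()
  if (n_discriminative > 0L) {
    eff <- study$truth$effect_profiles[[as.character(target_cluster)]]
    driver <- rownames(eff)[which.max(apply(abs(eff), 1L, max))]
    pool <- study$truth$true_markers[[driver]]
    if (set_size > length(pool)) stop("set_size exceeds the shifted-gene pool")
    for (i in seq_len(n_discriminative)) {
      sets[[sprintf("planted_%02d", i)]] <- sample(pool, set_size)
    }
  }
  n_random <- n_sets - n_discriminative
  for (i in seq_len(n_random)) {
    sets[[sprintf("random_%03d", i)]] <- sample(universe, set_size)
  }
  attr(sets, "descriptions") <- stats::setNames(
    ifelse(startsWith(names(sets), "planted_"), "planted discriminative set", "random set"),
    names(sets))
  attr(sets, "planted") <- grep("^planted_", names(sets), value = TRUE)
  sets
}
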