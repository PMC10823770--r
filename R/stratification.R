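#' Filter compounds by peak ALT elevation
#'
#' Retains compounds whose maximum ALT across treated samples at times up to
#' `max_time_h` reaches the threshold, mirroring the selection of
#' hepatotoxic conditions before trafficking stratification.
#'
#' @param meta Sample metadata with an `alt` column (IU/l).
#' @param threshold ALT threshold (default 65 IU/l).
#' @param max_time_h Latest time considered (default 24 h).
#' @return Character vector of retained compound names (sorted).
#' @export
filter_compounds_by_alt <- function(meta, threshold = 65, max_time_h = 24) {
  if (!("alt" %in% colnames(meta)) || all(is.na(meta$alt))) {
    stop("no ALT data in metadata")
  }
  treated <- meta[!meta$is_control & meta$time_h <= max_time_h & !is.na(meta$alt), ]
  if (!nrow(treated)) stop("no treated samples with ALT within the time window")
  peak <- tapply(treated$alt, treated$compound, max)
  sort(names(peak)[peak >= threshold])
}

#' Assemble per-compound immune-trafficking features
#'
#' One row per compound; the entry for (cell type, time) is the mean over
#' replicates of the control-z-scored estimate at that time. Defaults use
#' the four cell types whose estimates validate well (monocytes,
#' neutrophils, CD4 T, CD8 T) at 3, 6, 9, 24 h, giving 16 features.
#'
#' @param z_scores Cell-types x samples matrix z-scored against controls
#'   ([zscore_vs_control()]).
#' @param meta Sample metadata.
#' @param compounds Compounds to include (default: all treated compounds,
#'   typically the [filter_compounds_by_alt()] survivors).
#' @param cell_types Cell types used as features.
#' @param times_h Times used as features (hours).
#' @return Compounds x features matrix; feature names `"<cell>@<time>h"`.
#' @export
assemble_trafficking_features <- function(z_scores, meta, compounds = NULL,
                                          cell_types = c("Mon", "Neu", "CD4T", "CD8T"),
                                          times_h = c(3, 6, 9, 24)) {
  stopifnot(is.matrix(z_scores))
  miss_ct <- setdiff(cell_types, rownames(z_scores))
  if (length(miss_ct)) stop("cell types absent from scores: ", paste(miss_ct, collapse = ", "))
  m <- meta[match(colnames(z_scores), meta$sample_id), ]
  if (is.null(compounds)) compounds <- sort(unique(m$compound[!m$is_control]))
  fnames <- as.vector(t(outer(cell_types, times_h, function(ct, t) sprintf("%s@%gh", ct, t))))
  out <- matrix(NA_real_, nrow = length(compounds), ncol = length(fnames),
                dimnames = list(compounds, fnames))
  gaps <- character(0)
  for (cmp in compounds) {
    for (t in times_h) {
      ix <- which(m$compound == cmp & m$time_h == t & !m$is_control)
      if (!length(ix)) { gaps <- c(gaps, sprintf("%s@%gh", cmp, t)); next }
      for (ct in cell_types) {
        out[cmp, sprintf("%s@%gh", ct, t)] <- mean(z_scores[ct, ix])
      }
    }
  }
  if (length(gaps)) {
    stop("missing (compound, time) cells: ", paste(utils::head(gaps, 10L), collapse = ", "))
  }
  out
}

#' Assemble per-compound transcriptome features
#'
#' Per-gene-per-time features: expression is log-transformed (`log(x + 1)`),
#' replicates of each (compound, time) are averaged, and each feature is
#' z-scored across compounds. Features constant across compounds are dropped
#' with a warning.
#'
#' @param expr Genes x samples linear-scale expression matrix.
#' @param meta Sample metadata.
#' @param compounds Compounds to include (default: all treated).
#' @param times_h Times used (default 3, 6, 9, 24 h).
#' @return Compounds x (gene, time) matrix of z-scored features.
#' @export
assemble_transcriptome_features <- function(expr, meta, compounds = NULL,
                                            times_h = c(3, 6, 9, 24)) {
  stopifnot(is.matrix(expr))
  m <- meta[match(colnames(expr), meta$sample_id), ]
  if (is.null(compounds)) compounds <- sort(unique(m$compound[!m$is_control]))
  lx <- log(expr + 1)
  blocks <- lapply(times_h, function(t) {
    cols <- vapply(compounds, function(cmp) {
      ix <- which(m$compound == cmp & m$time_h == t & !m$is_control)
      if (!length(ix)) stop("missing (compound, time) cell: ", cmp, "@", t, "h")
      rowMeans(lx[, ix, drop = FALSE])
    }, numeric(nrow(lx)))
    t(cols)
  })
  feats <- do.call(cbind, blocks)
  colnames(feats) <- as.vector(vapply(times_h, function(t) {
    sprintf("%s@%gh", rownames(expr), t)
  }, character(nrow(expr))))
  rownames(feats) <- compounds
  sdv <- apply(feats, 2L, stats::sd)
  if (any(sdv == 0)) {
    warning(sum(sdv == 0), " constant feature(s) dropped")
    feats <- feats[, sdv > 0, drop = FALSE]
    sdv <- sdv[sdv > 0]
  }
  scale(feats, center = TRUE, scale = sdv)
}

#' Combine candidate embeddings into a spectral meta-distance
#'
#' For each point i: (1) its distance vector to all other points in each
#' candidate is normalized to unit L2 norm; (2) the K x K matrix of inner
#' products between normalized vectors measures how much candidates agree
#' around i; (3) the leading eigenvector of that matrix (entries taken in
#' absolute value, renormalized to sum 1; uniform on a tied leading
#' eigenvalue) gives per-candidate weights; (4) the meta-distance row is the
#' weighted sum of the candidate distances, each candidate scaled by one
#' global factor (the Frobenius norm of its distance matrix) so candidates
#' with arbitrary coordinate scales are commensurable; (5) the matrix is
#' symmetrized and its diagonal set to exactly 0. The global (rather than
#' per-row) scaling in step 4 makes the combination exactly rank-preserving
#' when all candidates agree: duplicated candidates give back a matrix
#' proportional to their common distance matrix. Candidates sitting at a
#' single point (zero distance vector around i) are excluded for that row
#' with a warning.
#'
#' @param emb An `embedding_set` from [embed_candidates()].
#' @return List of class `meta_distance`: `matrix` (n x n symmetric,
#'   non-negative, zero diagonal), `weights` (n x K, rows sum to 1),
#'   `methods`.
#' @export
meta_combine <- function(emb) {
  stopifnot(inherits(emb, "embedding_set"), length(emb$coords) >= 1L)
  K <- length(emb$coords)
  ids <- rownames(emb$coords[[1L]])
  n <- length(ids)
  Dk <- lapply(emb$coords, function(co) as.matrix(stats::dist(co)))
  gscale <- vapply(Dk, function(D) sqrt(sum(D^2)), 0)
  if (any(gscale == 0)) {
    warning("candidate(s) ", paste(names(Dk)[gscale == 0], collapse = ", "),
            " have all points coincident; excluded entirely")
    Dk <- Dk[gscale > 0]
    gscale <- gscale[gscale > 0]
    if (!length(Dk)) stop("no usable embedding candidate")
  }
  K <- length(Dk)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  W <- matrix(0, n, K, dimnames = list(ids, names(Dk)))
  for (i in seq_len(n)) {
    vecs <- lapply(Dk, function(D) D[i, -i])
    norms <- vapply(vecs, function(v) sqrt(sum(v^2)), 0)
    ok <- norms > 0
    if (!all(ok)) {
      warning("candidate(s) ", paste(names(vecs)[!ok], collapse = ", "),
              " have all-identical points at row ", ids[i], "; excluded for that row")
    }
    if (!any(ok)) stop("no usable candidate for point ", ids[i])
    V <- vapply(which(ok), function(k) vecs[[k]] / norms[k], numeric(n - 1L))
    C <- crossprod(V)
    ev <- eigen(C, symmetric = TRUE)
    if (length(ev$values) > 1L &&
        abs(ev$values[1L] - ev$values[2L]) < 1e-12 * max(1, abs(ev$values[1L]))) {
      w <- rep(1 / sum(ok), sum(ok))
    } else {
      w <- abs(ev$vectors[, 1L])
      w <- w / sum(w)
    }
    W[i, which(ok)] <- w
    G <- vapply(which(ok), function(k) vecs[[k]] / gscale[k], numeric(n - 1L))
    M[i, -i] <- as.numeric(G %*% w)
  }
  M <- (M + t(M)) / 2
  diag(M) <- 0
  structure(list(matrix = M, weights = W, methods = names(emb$coords)),
            class = "meta_distance")
}

#' Hierarchically cluster compounds on the meta-distance
#'
#' Agglomerative clustering (average linkage by default) on the precomputed
#' meta-distance. Cluster labels are renumbered deterministically: by
#' increasing cluster size, ties by the lexicographically first member.
#'
#' @param md A `meta_distance` from [meta_combine()] (or a symmetric
#'   dissimilarity matrix).
#' @param n_clusters Number of clusters to cut (default 4).
#' @param linkage `stats::hclust` agglomeration method (default
#'   `"average"`; Ward is not meaningful on a non-Euclidean meta-distance).
#' @return List of class `cluster_assignment`: `assignment` (named integer
#'   vector compound -> label in 1..n_clusters), `hclust` (the linkage
#'   record), `n_clusters`.
#' @export
hierarchical_cluster <- function(md, n_clusters = 4, linkage = "average") {
  m <- if (inherits(md, "meta_distance")) md$matrix else as.matrix(md)
  n <- nrow(m)
  if (n_clusters < 2L || n_clusters > n) stop("n_clusters must be in [2, n]")
  hc <- stats::hclust(stats::as.dist(m), method = linkage)
  raw <- stats::cutree(hc, k = n_clusters)
  size <- table(raw)
  first <- vapply(names(size), function(l) min(names(raw)[raw == l]), "")
  ord <- order(as.integer(size), first)
  relabel <- stats::setNames(seq_along(ord), names(size)[ord])
  assignment <- stats::setNames(as.integer(relabel[as.character(raw)]), names(raw))
  structure(list(assignment = assignment, hclust = hc, n_clusters = n_clusters),
            class = "cluster_assignment")
}

#' Per-cluster time-course summary with 95% confidence intervals
#'
#' For each cluster, feature and time: mean over all samples of the
#' cluster's compounds, with a normal-approximation 95% CI
#' (mean +/- 1.96 SE). A cell with a single sample reports its mean with
#' the CI flagged undefined rather than fabricated.
#'
#' @param values Features x samples matrix (z-scored trafficking estimates
#'   or hematology analytes).
#' @param meta Sample metadata.
#' @param assignment A `cluster_assignment` (or named integer vector
#'   compound -> cluster).
#' @param times_h Times summarized (default 3, 6, 9, 24 h).
#' @return Data.frame with columns `cluster`, `feature`, `time_h`, `n`,
#'   `mean`, `ci_lo`, `ci_hi`, `ci_defined`.
#' @export
summarize_time_course <- function(values, meta, assignment,
                                  times_h = c(3, 6, 9, 24)) {
  lab <- if (inherits(assignment, "cluster_assignment")) assignment$assignment else assignment
  m <- meta[match(colnames(values), meta$sample_id), ]
  rows <- list()
  for (cl in sort(unique(lab))) {
    cmps <- names(lab)[lab == cl]
    for (feat in rownames(values)) {
      for (t in times_h) {
        ix <- which(m$compound %in% cmps & m$time_h == t & !m$is_control)
        if (!length(ix)) next
        v <- values[feat, ix]
        n <- length(v)
        mu <- mean(v)
        if (n >= 2L) {
          se <- stats::sd(v) / sqrt(n)
          rows[[length(rows) + 1L]] <- data.frame(
            cluster = cl, feature = feat, time_h = t, n = n, mean = mu,
            ci_lo = mu - 1.96 * se, ci_hi = mu + 1.96 * se, ci_defined = TRUE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            cluster = cl, feature = feat, time_h = t, n = n, mean = mu,
            ci_lo = NA_real_, ci_hi = NA_real_, ci_defined = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' 2-D consensus layout of the meta-distance
#'
#' Metric MDS of the meta-distance for plotting; cosmetic only, never used
#' for clustering.
#'
#' @param md A `meta_distance`.
#' @return n x 2 coordinate matrix.
#' @export
meta_layout <- function(md) {
  co <- stats::cmdscale(stats::as.dist(md$matrix), k = 2L)
  colnames(co) <- c("dim1", "dim2")
  co
}
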