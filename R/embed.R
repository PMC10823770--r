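# Locally linear embedding and spectral embedding are implemented here
# directly (standard algorithms, small n); the other four candidates are
# delegated to stats, Rtsne and uwot.

# LLE: reconstruct each point from its k nearest neighbours, then take the
# bottom non-trivial eigenvectors of (I - W)'(I - W). Local Gram matrices
# are ridge-regularized so duplicate points stay well-posed.
.embed_lle <- function(x, k, ndim = 2L) {
  n <- nrow(x)
  D <- as.matrix(stats::dist(x))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[-1L][seq_len(k)]
    Z <- sweep(x[nb, , drop = FALSE], 2L, x[i, ])
    G <- tcrossprod(Z)
    G <- G + diag(k) * (1e-3 * sum(diag(G)) / k + 1e-12)
    w <- solve(G, rep(1, k))
    W[i, nb] <- w / sum(w)
  }
  M <- crossprod(diag(n) - W)
  ev <- eigen(M, symmetric = TRUE)
  idx <- order(ev$values)[seq(2L, ndim + 1L)]
  ev$vectors[, idx, drop = FALSE]
}

# Spectral embedding: symmetric kNN graph with Gaussian affinities (local
# sigma = median kNN distance), eigenvectors 2..(ndim+1) of the symmetric
# normalized Laplacian.
.embed_spectral <- function(x, k, ndim = 2L) {
  n <- nrow(x)
  D <- as.matrix(stats::dist(x))
  A <- matrix(0, n, n)
  sigma <- stats::median(apply(D, 1L, function(d) sort(d)[k + 1L]))
  if (sigma == 0) sigma <- 1
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[-1L][seq_len(k)]
    A[i, nb] <- exp(-D[i, nb]^2 / (2 * sigma^2))
  }
  A <- pmax(A, t(A))
  deg <- pmax(rowSums(A), 1e-12)
  L <- diag(n) - diag(1 / sqrt(deg)) %*% A %*% diag(1 / sqrt(deg))
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE)
  idx <- order(ev$values)[seq(2L, ndim + 1L)]
  ev$vectors[, idx, drop = FALSE]
}

#' Build the ensemble of candidate 2-D embeddings
#'
#' Produces one 2-D embedding of the compound feature table per method:
#' locally linear embedding, metric multidimensional scaling, spectral
#' embedding, principal component analysis, t-SNE, and UMAP. Stochastic
#' methods are made deterministic by the seed. Small-n safeguards: t-SNE
#' perplexity `min(5, floor((n-1)/3))`, neighbour counts `min(15, n-1)`,
#' LLE neighbours `min(5, n-2)`; a method that cannot run at the given n is
#' dropped with a warning.
#'
#' @param feats Compounds x features numeric matrix (z-scored features).
#' @param seed Integer seed shared by all stochastic methods.
#' @return List of class `embedding_set`: `coords` (named list of n x 2
#'   matrices with the compound ids as rownames), `seed`.
#' @export
embed_candidates <- function(feats, seed = 0) {
  stopifnot(is.matrix(feats))
  if (anyNA(feats)) stop("feature table contains missing values")
  n <- nrow(feats)
  if (n < 6L) stop("need >= 6 compounds to build the embedding ensemble")
  coords <- list()
  drop_note <- function(m, e) warning("candidate '", m, "' dropped: ", conditionMessage(e))

  set.seed(seed)
  coords$lle <- tryCatch(.embed_lle(feats, k = min(5L, n - 2L)),
                         error = function(e) { drop_note("lle", e); NULL })
  coords$mds <- tryCatch(stats::cmdscale(stats::dist(feats), k = 2L),
                         error = function(e) { drop_note("mds", e); NULL })
  coords$spectral <- tryCatch(.embed_spectral(feats, k = min(15L, n - 1L)),
                              error = function(e) { drop_note("spectral", e); NULL })
  coords$pca <- tryCatch(stats::prcomp(feats, center = TRUE, scale. = FALSE)$x[, 1:2, drop = FALSE],
                         error = function(e) { drop_note("pca", e); NULL })
  perplexity <- min(5, floor((n - 1) / 3))
  set.seed(seed)
  coords$tsne <- tryCatch({
    if (perplexity < 1) stop("n too small for t-SNE perplexity >= 1")
    Rtsne::Rtsne(feats, dims = 2L, perplexity = perplexity, pca = FALSE,
                 check_duplicates = FALSE, max_iter = 500L, verbose = FALSE,
                 num_threads = 1L)$Y
  }, error = function(e) { drop_note("tsne", e); NULL })
  set.seed(seed)
  coords$umap <- tryCatch(
    uwot::umap(feats, n_neighbors = min(15L, n - 1L), n_components = 2L,
               n_threads = 1L, n_sgd_threads = 1L, verbose = FALSE),
    error = function(e) { drop_note("umap", e); NULL })

  coords <- Filter(Negate(is.null), coords)
  coords <- lapply(coords, function(co) {
    co <- as.matrix(co)
    rownames(co) <- rownames(feats)
    colnames(co) <- c("dim1", "dim2")
    co
  })
  if (!length(coords)) stop("no embedding candidate could be computed")
  structure(list(coords = coords, seed = seed), class = "embedding_set")
}
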