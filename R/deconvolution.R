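#' Elastic-net configuration for cell-score estimation
#'
#' Defaults reproduce the penalized objective used throughout this package:
#' data term \eqn{\|y - Xp\|_2^2} with penalty
#' \eqn{\lambda[(1-\alpha)/2\,\|p\|_2^2 + \alpha \|p\|_1]}, \eqn{\lambda = 1},
#' \eqn{\alpha = 0.05}, no intercept, no predictor standardization.
#'
#' @param lam Overall penalty strength \eqn{\lambda \ge 0}.
#' @param alpha L1/L2 mixing \eqn{\alpha \in [0, 1]} (1 = lasso, 0 = ridge).
#' @param fit_intercept Fit an unpenalized per-sample intercept.
#' @param nonneg_clip Set negative estimates to 0 after solving.
#' @param max_iter Maximum coordinate-descent sweeps per sample.
#' @param tol Convergence tolerance on the maximum coordinate change.
#' @return List of class `enet_config`.
#' @export
enet_config <- function(lam = 1, alpha = 0.05, fit_intercept = FALSE,
                        nonneg_clip = FALSE, max_iter = 10000, tol = 1e-6) {
  stopifnot(lam >= 0, alpha >= 0, alpha <= 1, max_iter >= 1, tol > 0)
  structure(list(lam = lam, alpha = alpha, fit_intercept = fit_intercept,
                 nonneg_clip = nonneg_clip, max_iter = max_iter, tol = tol),
            class = "enet_config")
}

#' Elastic-net objective value
#'
#' \eqn{\|y - Xp\|_2^2 + \lambda[(1-\alpha)/2\,\|p\|_2^2 + \alpha\|p\|_1]},
#' evaluated exactly as the estimator minimizes it (no 1/(2n) factor).
#'
#' @param y Response vector (length N).
#' @param X N x K design matrix.
#' @param p Coefficient vector (length K).
#' @param lam,alpha Penalty strength and mixing.
#' @param intercept Optional intercept (default 0).
#' @return Scalar objective value.
#' @export
enet_objective <- function(y, X, p, lam, alpha, intercept = 0) {
  r <- y - X %*% p - intercept
  sum(r^2) + lam * ((1 - alpha) / 2 * sum(p^2) + alpha * sum(abs(p)))
}

# Coordinate descent on the un-normalized elastic-net objective for one
# response. Update for coordinate k with partial residual r:
#   p_k <- S(x_k' r, lam*alpha/2) / (x_k' x_k + lam*(1-alpha)/2)
.enet_cd <- function(y, X, lam, alpha, fit_intercept, max_iter, tol) {
  K <- ncol(X)
  p <- numeric(K)
  b0 <- 0
  xx <- colSums(X^2)
  denom <- xx + lam * (1 - alpha) / 2
  thr <- lam * alpha / 2
  r <- y  # residual y - X p - b0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    delta <- 0
    if (fit_intercept) {
      b0_new <- b0 + mean(r)
      r <- r - (b0_new - b0)
      delta <- max(delta, abs(b0_new - b0))
      b0 <- b0_new
    }
    for (k in seq_len(K)) {
      rho <- sum(X[, k] * r) + xx[k] * p[k]
      pk <- sign(rho) * max(abs(rho) - thr, 0) / denom[k]
      if (pk != p[k]) {
        r <- r - X[, k] * (pk - p[k])
        delta <- max(delta, abs(pk - p[k]))
        p[k] <- pk
      }
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  list(p = p, intercept = b0, converged = converged, iters = it)
}

#' Estimate per-sample cell-type scores by elastic-net regression
#'
#' Solves, independently for each sample column \eqn{y_j} of the bulk matrix,
#' \deqn{\hat p_j = \arg\min_p \|y_j - X p\|_2^2 +
#'   \lambda[(1-\alpha)/2\,\|p\|_2^2 + \alpha\|p\|_1]}
#' by coordinate descent on exactly that objective. Estimates are reported
#' as unconstrained scores (no sum-to-one renormalization); downstream
#' analyses use z-scored variants.
#'
#' @param Y Genes x samples bulk matrix restricted to the signature's marker
#'   genes, same row order as `X`.
#' @param X N x K signature matrix (marker genes x cell types).
#' @param cfg An [enet_config()].
#' @return K x M score matrix (cell types x samples) with attribute
#'   `scale_tag = "raw"`; non-convergent columns trigger one warning.
#' @export
fit_proportions <- function(Y, X, cfg = enet_config()) {
  stopifnot(is.matrix(Y), is.matrix(X), inherits(cfg, "enet_config"))
  if (!identical(rownames(Y), rownames(X))) {
    stop("gene ids/order of Y and X do not match; restrict Y to the signature genes first")
  }
  M <- ncol(Y); K <- ncol(X)
  P <- matrix(NA_real_, nrow = K, ncol = M, dimnames = list(colnames(X), colnames(Y)))
  bad <- character(0)
  for (j in seq_len(M)) {
    fit <- .enet_cd(Y[, j], X, cfg$lam, cfg$alpha, cfg$fit_intercept,
                    cfg$max_iter, cfg$tol)
    if (!fit$converged) bad <- c(bad, colnames(Y)[j])
    P[, j] <- fit$p
  }
  if (length(bad)) {
    warning("coordinate descent did not converge within max_iter for sample(s): ",
            paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (cfg$nonneg_clip) P[P < 0] <- 0
  attr(P, "scale_tag") <- "raw"
  P
}

#' Proximal-gradient reference solver for the elastic-net objective
#'
#' Independent first-order solver (ISTA with backtracking-free fixed step
#' from the Lipschitz constant) for the same objective as
#' [fit_proportions()]. Used as a cross-check oracle in tests and in the
#' acceptance analysis; not the production path.
#'
#' @param y Response vector.
#' @param X Design matrix.
#' @param lam,alpha Penalty parameters.
#' @param max_iter Iterations.
#' @return List with `p` and the attained `objective`.
#' @export
enet_prox_reference <- function(y, X, lam, alpha, max_iter = 20000) {
  K <- ncol(X)
  L <- 2 * max(eigen(crossprod(X), symmetric = TRUE, only.values = TRUE)$values) +
    lam * (1 - alpha)
  step <- 1 / L
  p <- numeric(K)
  thr <- step * lam * alpha
  for (i in seq_len(max_iter)) {
    grad <- -2 * crossprod(X, y - X %*% p) + lam * (1 - alpha) * p
    z <- p - step * grad
    p_new <- sign(z) * pmax(abs(z) - thr, 0)
    if (max(abs(p_new - p)) < 1e-12) { p <- p_new; break }
    p <- p_new
  }
  list(p = as.numeric(p), objective = enet_objective(y, X, p, lam, alpha))
}

#' Z-score estimates against matched vehicle controls
#'
#' For every cell type and control group (linked by `control_group_key`):
#' \eqn{z = (v - \mathrm{mean}(controls)) / \mathrm{sd}(controls)}, sample
#' SD (n-1 denominator). Control samples are transformed with their own
#' group statistics, so each transformed control block has per-feature
#' mean 0.
#'
#' @param scores Cell-types x samples matrix (raw scores or any per-sample
#'   measurement keyed by the same sample ids).
#' @param meta Sample metadata with `sample_id`, `is_control`,
#'   `control_group_key`.
#' @return Matrix of the same shape, attribute
#'   `scale_tag = "zscore_vs_control"`.
#' @export
zscore_vs_control <- function(scores, meta) {
  stopifnot(is.matrix(scores))
  meta <- validate_metadata(meta)
  miss <- setdiff(colnames(scores), meta$sample_id)
  if (length(miss)) stop("samples missing from metadata: ", paste(utils::head(miss), collapse = ", "))
  m <- meta[match(colnames(scores), meta$sample_id), ]
  out <- scores
  for (key in unique(m$control_group_key)) {
    in_group <- which(m$control_group_key == key)
    ctrl <- in_group[m$is_control[in_group]]
    if (length(ctrl) < 2L) {
      stop("control group '", key, "' has fewer than 2 control samples")
    }
    mu <- rowMeans(scores[, ctrl, drop = FALSE])
    sdv <- apply(scores[, ctrl, drop = FALSE], 1L, stats::sd)
    if (any(sdv == 0)) {
      stop("zero control SD for cell type '", rownames(scores)[which(sdv == 0)[1L]],
           "' in control group '", key, "'")
    }
    out[, in_group] <- (scores[, in_group, drop = FALSE] - mu) / sdv
  }
  attr(out, "scale_tag") <- "zscore_vs_control"
  out
}

#' Z-score each feature across a set of compared samples
#'
#' Per row (cell type or analyte), subtract the mean and divide by the
#' sample SD (n-1 denominator) across the compared samples.
#'
#' @param values Features x samples matrix, or a numeric vector.
#' @param samples Optional character vector restricting the comparison to a
#'   sample subset (default: all columns).
#' @return Transformed matrix (or vector) with attribute
#'   `scale_tag = "zscore_between_samples"`; per-feature mean 0 and SD 1.
#' @export
zscore_between_samples <- function(values, samples = NULL) {
  vec <- is.null(dim(values))
  v <- if (vec) matrix(values, nrow = 1L, dimnames = list(NULL, names(values))) else values
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  if (ncol(v) < 2L) stop("need >= 2 samples to z-score between samples")
  mu <- rowMeans(v)
  sdv <- apply(v, 1L, stats::sd)
  if (any(sdv == 0)) {
    stop("zero variance across compared samples for feature ",
         if (!is.null(rownames(v))) paste0("'", rownames(v)[which(sdv == 0)[1L]], "'")
         else which(sdv == 0)[1L])
  }
  z <- (v - mu) / sdv
  if (vec) z <- stats::setNames(as.numeric(z), colnames(v))
  attr(z, "scale_tag") <- "zscore_between_samples"
  z
}
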