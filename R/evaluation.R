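#' Aggregate per-sample values into per-condition medians
#'
#' Collapses replicates of each (compound, dose, time) condition to their
#' median, per feature, for concordance plotting against measured fractions.
#'
#' @param values Features x samples matrix (scores or measurements).
#' @param meta Sample metadata covering every column of `values`.
#' @param by Metadata columns defining a condition
#'   (default `compound`, `dose_group`, `time_h`).
#' @return List with `values` (features x conditions median matrix) and
#'   `conditions` (data.frame describing each column).
#' @export
aggregate_condition_medians <- function(values, meta,
                                        by = c("compound", "dose_group", "time_h")) {
  stopifnot(is.matrix(values))
  m <- meta[match(colnames(values), meta$sample_id), ]
  if (anyNA(m$sample_id)) stop("samples missing from metadata")
  key <- do.call(paste, c(m[by], sep = "|"))
  groups <- split(seq_len(ncol(values)), key)
  if (any(lengths(groups) == 0L)) stop("empty condition group")
  med <- vapply(groups, function(ix) {
    apply(values[, ix, drop = FALSE], 1L, stats::median)
  }, numeric(nrow(values)))
  med <- matrix(med, nrow = nrow(values),
                dimnames = list(rownames(values), names(groups)))
  cond <- m[!duplicated(key), by, drop = FALSE]
  cond <- cond[match(names(groups), do.call(paste, c(cond[by], sep = "|"))), , drop = FALSE]
  rownames(cond) <- names(groups)
  list(values = med, conditions = cond)
}

#' Concordance between estimated and measured cell fractions
#'
#' Per cell type, both sides are first z-scored across the compared points
#' (unless `zscore = FALSE`), then Pearson correlation and an ordinary
#' least-squares fit of estimated on measured are reported. Pearson r is
#' unchanged by the z-scoring (affine invariance); slope and intercept are
#' reported on the z scale.
#'
#' @param estimated Cell-types x points matrix of deconvolution estimates.
#' @param measured Matrix of the same shape and dimnames with measured
#'   fractions (e.g. flow cytometry percent-of-cells).
#' @param zscore Z-score both sides across points first (default TRUE).
#' @return Data.frame with one row per cell type: `cell_type`, `pearson_r`,
#'   `slope`, `intercept`, `n_points`.
#' @export
concordance <- function(estimated, measured, zscore = TRUE) {
  stopifnot(is.matrix(estimated), is.matrix(measured))
  if (!identical(dim(estimated), dim(measured)) ||
      !identical(rownames(estimated), rownames(measured))) {
    stop("estimated and measured must share shape and cell types")
  }
  if (ncol(estimated) < 3L) stop("need >= 3 paired points per cell type")
  if (zscore) {
    estimated <- zscore_between_samples(estimated)
    measured <- zscore_between_samples(measured)
  }
  res <- lapply(rownames(estimated), function(ct) {
    x <- measured[ct, ]; y <- estimated[ct, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop("zero variance for cell type '", ct, "'")
    }
    fit <- stats::lm(y ~ x)
    data.frame(cell_type = ct,
               pearson_r = stats::cor(x, y),
               slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]),
               n_points = length(x), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
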