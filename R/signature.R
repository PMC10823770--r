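#' Collapse sorted-cell replicates into one reference profile per cell type
#'
#' @param ref_raw Genes x samples matrix of sorted-cell expression.
#' @param cell_type_of_sample Named character vector mapping every sample id
#'   to its cell type.
#' @return Genes x cell-types matrix: per-gene arithmetic mean over the
#'   replicates of each type. Cell types are ordered by first appearance.
#' @export
collapse_replicates <- function(ref_raw, cell_type_of_sample) {
  stopifnot(is.matrix(ref_raw), !is.null(colnames(ref_raw)))
  miss <- setdiff(colnames(ref_raw), names(cell_type_of_sample))
  if (length(miss)) stop("samples without a cell type label: ", paste(miss, collapse = ", "))
  labels <- cell_type_of_sample[colnames(ref_raw)]
  types <- unique(unname(labels))
  if (length(types) < 2L) stop("need >= 2 cell types")
  out <- vapply(types, function(k) {
    rowMeans(ref_raw[, labels == k, drop = FALSE])
  }, numeric(nrow(ref_raw)))
  dimnames(out) <- list(rownames(ref_raw), types)
  out
}

#' Restrict reference profiles and a bulk matrix to their common genes
#'
#' Only genes present in both matrices are retained, in sorted order, so
#' marker selection never proposes a gene the bulk matrix cannot supply.
#'
#' @param ref Genes x cell-types reference profile matrix.
#' @param mixture Genes x samples bulk expression matrix.
#' @return List with elements `ref` and `mixture`, both restricted to the
#'   sorted gene intersection.
#' @export
intersect_genes <- function(ref, mixture) {
  common <- sort(intersect(rownames(ref), rownames(mixture)))
  if (!length(common)) stop("reference and mixture share no genes")
  list(ref = ref[common, , drop = FALSE], mixture = mixture[common, , drop = FALSE])
}

#' Select cell-type marker genes by fold change against all other types
#'
#' A gene qualifies as a marker of cell type k iff its (pseudocounted)
#' expression exceeds `fc_threshold` times that of EVERY other cell type;
#' equivalently, the ratio against the strongest competitor
#' `(x_k + pc) / (max_{j != k} x_j + pc)` exceeds the threshold. Qualifying
#' genes are ranked by that ratio, descending (ties broken by gene id), and
#' truncated to `max_genes` per type. Qualification against all other types
#' makes the marker lists disjoint by construction.
#'
#' @param ref Genes x cell-types reference profiles, linear scale, collapsed
#'   and intersected with the bulk gene space.
#' @param fc_threshold Fold-change threshold a marker must exceed against
#'   every other cell type (default 1.5).
#' @param max_genes Per-type cap on retained markers (default 200).
#' @param pseudocount Added to numerator and denominator before the ratio to
#'   stabilize zero denominators (default 1).
#' @return Named list (class `marker_set`): per cell type, a data.frame with
#'   columns `gene` and `ratio`, ordered by decreasing enrichment ratio.
#' @export
select_markers <- function(ref, fc_threshold = 1.5, max_genes = 200, pseudocount = 1) {
  stopifnot(is.matrix(ref), ncol(ref) >= 2L)
  types <- colnames(ref)
  x <- ref + pseudocount
  out <- lapply(seq_along(types), function(k) {
    others <- x[, -k, drop = FALSE]
    max_other <- do.call(pmax, as.data.frame(others))
    ratio <- x[, k] / max_other
    keep <- which(ratio > fc_threshold)
    if (!length(keep)) {
      warning("no marker genes qualify for cell type '", types[k], "'")
      return(data.frame(gene = character(0), ratio = numeric(0)))
    }
    ord <- keep[order(-ratio[keep], rownames(ref)[keep])]
    ord <- ord[seq_len(min(max_genes, length(ord)))]
    data.frame(gene = rownames(ref)[ord], ratio = unname(ratio[ord]),
               stringsAsFactors = FALSE)
  })
  names(out) <- types
  structure(out, class = "marker_set")
}

#' Build the signature matrix from reference profiles and selected markers
#'
#' Rows are the concatenated marker lists in cell-type order; values are
#' copied from the reference profiles on linear scale.
#'
#' @param ref Genes x cell-types reference profiles.
#' @param markers A `marker_set` from [select_markers()] derived from `ref`.
#' @return N x K numeric matrix (marker genes x cell types).
#' @export
build_signature <- function(ref, markers) {
  genes <- unlist(lapply(markers, `[[`, "gene"), use.names = FALSE)
  if (!length(genes)) stop("all marker lists are empty; cannot build a signature")
  if (anyDuplicated(genes)) stop("marker lists are not disjoint")
  miss <- setdiff(genes, rownames(ref))
  if (length(miss)) stop("markers absent from reference: ", paste(utils::head(miss), collapse = ", "))
  ref[genes, , drop = FALSE]
}
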