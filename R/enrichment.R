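#' Single-sample gene-set enrichment score (rank-weighted running sum)
#'
#' Genes are ranked by expression, descending (ties broken by gene id); the
#' gene at rank position i (1 = highest) gets rank value r_i = N - i + 1 and,
#' if it belongs to the set, weight w_i = r_i^tau. The score is the sum over
#' positions of the difference between the weighted in-set cumulative
#' fraction and the unweighted out-of-set cumulative fraction:
#' \deqn{ES = \sum_i [P_{in}(i) - P_{out}(i)]}
#' with \eqn{P_{in}(i) = \sum_{j \le i, j \in S} w_j / \sum_{j \in S} w_j}
#' and \eqn{P_{out}(i) = |\{j \le i, j \notin S\}| / (N - |S|)}. With
#' `normalize = TRUE` the sum is divided by N. Being rank-based, the score
#' is invariant under strictly monotone transforms of the expression values.
#'
#' @param expr_sample Named numeric vector: one sample's expression by gene.
#' @param gene_set Character vector of set genes.
#' @param tau Rank-weight exponent (default 0.75; 0 gives the unweighted
#'   cumulative fraction).
#' @param normalize Divide the running-sum total by N (default TRUE).
#' @return Scalar enrichment score.
#' @export
ssgsea_score <- function(expr_sample, gene_set, tau = 0.75, normalize = TRUE) {
  stopifnot(is.numeric(expr_sample), !is.null(names(expr_sample)))
  N <- length(expr_sample)
  in_set <- names(expr_sample) %in% gene_set
  n_in <- sum(in_set)
  if (n_in == 0L) stop("no gene of the set is present in the sample")
  if (n_in == N) stop("gene set equals the gene universe; out-of-set fraction undefined")
  ord <- order(-expr_sample, names(expr_sample))
  in_ord <- in_set[ord]
  r <- N - seq_len(N) + 1
  w <- ifelse(in_ord, r^tau, 0)
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_ord) / (N - n_in)
  es <- sum(p_in - p_out)
  if (normalize) es <- es / N
  es
}

#' ssGSEA score table over samples and gene sets
#'
#' Each set is first intersected with the matrix's genes; sets falling below
#' `min_size` present genes are dropped with a warning. Scores are computed
#' per sample per set (replicate samples kept as-is).
#'
#' @param expr Genes x samples expression matrix.
#' @param sets Named list of gene sets ([read_gmt()]).
#' @param tau,normalize Passed to [ssgsea_score()].
#' @param min_size Minimum number of set genes present (default 3).
#' @return Samples x sets numeric matrix with attributes `tau` and
#'   `normalized`.
#' @export
score_table <- function(expr, sets, tau = 0.75, normalize = TRUE, min_size = 3) {
  stopifnot(is.matrix(expr))
  present <- lapply(sets, intersect, x = rownames(expr))
  keep <- lengths(present) >= min_size & lengths(present) < nrow(expr)
  if (any(!keep)) {
    warning(sum(!keep), " gene set(s) dropped (fewer than ", min_size,
            " genes present, or spanning the whole universe)")
  }
  if (!any(keep)) stop("all gene sets dropped")
  present <- present[keep]
  out <- matrix(NA_real_, nrow = ncol(expr), ncol = length(present),
                dimnames = list(colnames(expr), names(present)))
  for (j in seq_len(ncol(expr))) {
    v <- expr[, j]
    names(v) <- rownames(expr)
    for (s in seq_along(present)) {
      out[j, s] <- ssgsea_score(v, present[[s]], tau = tau, normalize = normalize)
    }
  }
  attr(out, "tau") <- tau
  attr(out, "normalized") <- normalize
  out
}

#' Cluster-discriminative gene sets by rank-sum tests
#'
#' For every (cluster, set) pair, a two-sided Mann-Whitney U test compares
#' the set's enrichment scores in the cluster's samples against all other
#' clusters' samples, with Bonferroni adjustment across sets within each
#' cluster contrast. Direction is the sign of the median difference.
#'
#' @param scores Samples x sets matrix from [score_table()].
#' @param assignment A `cluster_assignment` (or named vector
#'   compound -> cluster).
#' @param meta Sample metadata mapping sample ids to compounds.
#' @param alpha Significance level recorded with the result (default 0.05).
#' @param test `"wilcox"` (default) or `"t"`.
#' @param adjust Multiplicity correction passed to [stats::p.adjust()]
#'   (default `"bonferroni"`).
#' @return Data.frame sorted by `adjusted_p`: `set_name`, `cluster`,
#'   `raw_p`, `adjusted_p`, `direction` (`"up"`/`"down"`).
#' @export
discriminative_terms <- function(scores, assignment, meta, alpha = 0.05,
                                 test = c("wilcox", "t"), adjust = "bonferroni") {
  test <- match.arg(test)
  lab <- if (inherits(assignment, "cluster_assignment")) assignment$assignment else assignment
  m <- meta[match(rownames(scores), meta$sample_id), ]
  cluster_of_sample <- lab[m$compound]
  usable <- !is.na(cluster_of_sample)
  scores <- scores[usable, , drop = FALSE]
  cluster_of_sample <- cluster_of_sample[usable]
  clusters <- sort(unique(cluster_of_sample))
  if (length(clusters) < 2L) stop("need >= 2 clusters with scored samples")
  rows <- list()
  for (cl in clusters) {
    in_cl <- cluster_of_sample == cl
    if (sum(in_cl) < 2L) {
      warning("cluster ", cl, " has fewer than 2 samples; contrasts skipped")
      next
    }
    raw_p <- numeric(ncol(scores))
    direction <- character(ncol(scores))
    for (s in seq_len(ncol(scores))) {
      a <- scores[in_cl, s]; b <- scores[!in_cl, s]
      raw_p[s] <- if (test == "wilcox") {
        stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
      } else {
        stats::t.test(a, b)$p.value
      }
      if (is.na(raw_p[s])) raw_p[s] <- 1
      direction[s] <- if (stats::median(a) >= stats::median(b)) "up" else "down"
    }
    rows[[as.character(cl)]] <- data.frame(
      set_name = colnames(scores), cluster = cl, raw_p = raw_p,
      adjusted_p = stats::p.adjust(raw_p, method = adjust),
      direction = direction, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no cluster had enough samples for a contrast")
  out <- do.call(rbind, rows)
  out <- out[order(out$adjusted_p, out$raw_p, out$set_name), ]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}
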