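make_meta <- function(alt_by_cmp, time = 9) {
  cmps <- names(alt_by_cmp)
  rows <- lapply(cmps, function(cmp) {
    data.frame(sample_id = paste0(cmp, "_", seq_along(alt_by_cmp[[cmp]])),
               compound = cmp, dose_group = "high", time_h = time,
               replicate = seq_along(alt_by_cmp[[cmp]]), is_control = FALSE,
               control_group_key = "k", alt = alt_by_cmp[[cmp]])
  })
  ctrl <- data.frame(sample_id = c("c1", "c2"), compound = "veh", dose_group = "v",
                     time_h = time, replicate = 1:2, is_control = TRUE,
                     control_group_key = "k", alt = c(25, 30))
  rbind(do.call(rbind, rows), ctrl)
}

test_that("ALT filter keeps compounds whose peak ALT reaches the threshold", {
  meta <- make_meta(list(hi = c(40, 80), lo = c(30, 50)))
  expect_equal(filter_compounds_by_alt(meta), "hi")
  expect_setequal(filter_compounds_by_alt(meta, threshold = 0), c("hi", "lo"))
  # samples after the time window do not count
  late <- make_meta(list(only_late = c(200, 300)), time = 48)
  expect_error(filter_compounds_by_alt(late), "time window")
  meta$alt <- NULL
  expect_error(filter_compounds_by_alt(meta), "no ALT")
})

test_that("trafficking features average replicate z-scores into 16 columns", {
  st <- small_study(seed = 15)
  z <- zscore_vs_control(st$truth$true_proportions, st$meta)
  f <- assemble_trafficking_features(z, st$meta)
  expect_equal(dim(f), c(8L, 16L))
  expect_true(all(c("Neu@3h", "CD8T@24h") %in% colnames(f)))
  # hand-check one entry against the replicate mean
  m <- st$meta
  ix <- m$sample_id[m$compound == "cmp01" & m$time_h == 3 & !m$is_control]
  expect_equal(f["cmp01", "Neu@3h"], mean(z["Neu", ix]))
  # missing cells are reported
  sub <- m[!(m$compound == "cmp01" & m$time_h == 9), ]
  zsub <- z[, sub$sample_id]
  expect_error(assemble_trafficking_features(zsub, sub), "cmp01@9h")
})

test_that("null-study trafficking features stay near zero", {
  st <- small_study(seed = 16, effect_scale = 0)
  z <- zscore_vs_control(st$truth$true_proportions, st$meta)
  f <- assemble_trafficking_features(z, st$meta)
  expect_lt(max(abs(colMeans(f))), 3 / sqrt(3))
})

test_that("transcriptome features are z-scored per feature with constant genes dropped", {
  st <- small_study(seed = 17)
  expr <- st$expression[1:50, ]
  expr[3, ] <- 7  # constant gene
  expect_warning(f <- assemble_transcriptome_features(expr, st$meta), "constant")
  expect_equal(nrow(f), 8)
  expect_equal(ncol(f), (50 - 1) * 4)
  expect_lt(max(abs(colMeans(f))), 1e-12)
  expect_equal(unname(apply(f, 2, sd)), rep(1, ncol(f)))
})

test_that("embedding ensemble yields six deterministic 2-D candidates", {
  set.seed(20)
  feats <- matrix(rnorm(16 * 16), 16, 16,
                  dimnames = list(sprintf("cmp%02d", 1:16), paste0("f", 1:16)))
  emb <- embed_candidates(feats, seed = 5)
  expect_setequal(names(emb$coords),
                  c("lle", "mds", "spectral", "pca", "tsne", "umap"))
  for (co in emb$coords) expect_equal(dim(co), c(16L, 2L))
  emb2 <- embed_candidates(feats, seed = 5)
  expect_equal(emb$coords, emb2$coords)
  # duplicate input rows land on coincident points for distance-preserving methods
  feats2 <- feats; feats2[2, ] <- feats2[1, ]
  emb3 <- embed_candidates(feats2, seed = 5)
  expect_lt(max(abs(emb3$coords$mds[1, ] - emb3$coords$mds[2, ])), 1e-8)
  expect_lt(max(abs(emb3$coords$pca[1, ] - emb3$coords$pca[2, ])), 1e-8)
  expect_error(embed_candidates(feats[1:4, ]), ">= 6")
})

test_that("meta_combine: single candidate returns its globally scaled distances, weight 1", {
  set.seed(21)
  co <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("c", 1:10), NULL))
  emb <- structure(list(coords = list(pca = co), seed = 0), class = "embedding_set")
  md <- meta_combine(emb)
  expect_equal(unname(md$weights[, 1]), rep(1, 10))
  D <- as.matrix(dist(co))
  expect_equal(md$matrix, D / sqrt(sum(D^2)), tolerance = 1e-12)
})

test_that("meta_combine: duplicated candidates share weight equally, rank-preserving", {
  set.seed(22)
  co <- matrix(rnorm(24), 12, 2, dimnames = list(paste0("c", 1:12), NULL))
  emb <- structure(list(coords = list(a = co, b = co), seed = 0),
                   class = "embedding_set")
  md <- meta_combine(emb)
  expect_equal(unname(md$weights), matrix(0.5, 12, 2), tolerance = 1e-8)
  D <- as.matrix(dist(co))
  expect_equal(cor(as.dist(md$matrix), as.dist(D), method = "spearman"), 1)
  # exact proportionality, not just rank agreement
  expect_equal(md$matrix, D / sqrt(sum(D^2)), tolerance = 1e-10)
})

test_that("meta_combine favors the majority pair over a dissimilar candidate", {
  set.seed(23)
  A <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("c", 1:10), NULL))
  B <- matrix(rnorm(20, sd = 3), 10, 2, dimnames = list(paste0("c", 1:10), NULL))
  emb <- structure(list(coords = list(a1 = A, a2 = A, b = B), seed = 0),
                   class = "embedding_set")
  md <- meta_combine(emb)
  expect_true(all(md$weights[, "a1"] > md$weights[, "b"]))
  expect_true(all(md$weights[, "a2"] > md$weights[, "b"]))
  # independent eigen-oracle on one point's 3 x 3 comparison matrix
  i <- 1
  Dk <- lapply(list(A, A, B), function(co) as.matrix(dist(co)))
  V <- vapply(Dk, function(D) D[i, -i] / sqrt(sum(D[i, -i]^2)), numeric(9))
  w_oracle <- abs(eigen(crossprod(V), symmetric = TRUE)$vectors[, 1])
  w_oracle <- w_oracle / sum(w_oracle)
  expect_equal(unname(md$weights[i, ]), w_oracle, tolerance = 1e-10)
})

test_that("meta-distance is a valid dissimilarity, invariant to rigid motion", {
  set.seed(24)
  coords <- lapply(1:3, function(i) {
    matrix(rnorm(20), 10, 2, dimnames = list(paste0("c", 1:10), NULL))
  })
  names(coords) <- c("m1", "m2", "m3")
  emb <- structure(list(coords = coords, seed = 0), class = "embedding_set")
  md <- meta_combine(emb)
  expect_equal(md$matrix, t(md$matrix))
  expect_true(all(md$matrix >= 0))
  expect_identical(unname(diag(md$matrix)), rep(0, 10))
  expect_equal(unname(rowSums(md$weights)), rep(1, 10), tolerance = 1e-12)
  # rotate + translate one candidate: distances unchanged, meta-distance too
  th <- 0.77
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  coords2 <- coords
  coords2$m2 <- sweep(coords2$m2 %*% R, 2, c(5, -3), "+")
  rownames(coords2$m2) <- rownames(coords$m2)
  md2 <- meta_combine(structure(list(coords = coords2, seed = 0),
                                class = "embedding_set"))
  expect_equal(md$matrix, md2$matrix, tolerance = 1e-10)
})

test_that("hierarchical clustering cuts, relabels deterministically and errors sanely", {
  set.seed(25)
  blob1 <- matrix(rnorm(10, 0, 0.1), 5, 2)
  blob2 <- matrix(rnorm(14, 8, 0.1), 7, 2)
  x <- rbind(blob1, blob2)
  rownames(x) <- sprintf("c%02d", 1:12)
  md <- as.matrix(dist(x))
  cl <- hierarchical_cluster(md, n_clusters = 2)
  expect_equal(unname(cl$assignment[1:5]), rep(1L, 5))  # smaller cluster first
  expect_equal(unname(cl$assignment[6:12]), rep(2L, 7))
  cl_all <- hierarchical_cluster(md, n_clusters = 12)
  expect_equal(sort(unname(cl_all$assignment)), 1:12)   # singletons
  expect_error(hierarchical_cluster(md, n_clusters = 13), "n_clusters")
})

test_that("the full pipeline recovers planted clusters on a strong-effect study", {
  st <- simulate_study(seed = 4)
  pl <- suppressWarnings(run_trafficking_pipeline(st, seed = 4))
  expect_equal(ari(pl$clusters$assignment, st$truth$true_cluster), 1)
  expect_length(pl$compounds, 16)
})

test_that("time-course summaries carry normal 95% CIs with degenerate cells flagged", {
  st <- small_study(seed = 26)
  z <- zscore_vs_control(st$truth$true_proportions, st$meta)
  tc <- summarize_time_course(z[c("Neu", "Mon"), ], st$meta,
                              st$truth$true_cluster)
  expect_true(all(tc$ci_defined))
  row1 <- tc[1, ]
  cmps <- names(st$truth$true_cluster)[st$truth$true_cluster == row1$cluster]
  m <- st$meta
  ix <- m$sample_id[m$compound %in% cmps & m$time_h == row1$time_h & !m$is_control]
  expect_equal(row1$mean, mean(z[row1$feature, ix]))
  expect_equal(row1$ci_hi - row1$mean, 1.96 * sd(z[row1$feature, ix]) / sqrt(length(ix)))
  # single-sample cluster cell: CI undefined, not fabricated
  sub <- m[m$is_control | (m$compound == "cmp01" & m$replicate == 1), ]
  tc1 <- summarize_time_course(z[, sub$sample_id], sub,
                               c(cmp01 = 1L))
  expect_true(all(!tc1$ci_defined))
  expect_true(all(is.na(tc1$ci_lo)))
})
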