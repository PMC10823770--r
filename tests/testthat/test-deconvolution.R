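test_that("unregularized fit recovers exact coefficients on consistent systems", {
  inst <- random_enet_instance(n = 40, k = 5, seed = 2)
  p_true <- runif(5, 0, 2)
  y <- inst$X %*% p_true
  Y <- matrix(y, dimnames = list(rownames(inst$X), "s1"))
  fit <- fit_proportions(Y, inst$X, enet_config(lam = 0, tol = 1e-12))
  expect_lt(max(abs(fit[, 1] - p_true)), 1e-8)
  expect_identical(attr(fit, "scale_tag"), "raw")
})

test_that("pure ridge matches the closed form (X'X + lam/2 I)^-1 X'y", {
  for (s in 1:5) {
    inst <- random_enet_instance(seed = s)
    Y <- matrix(inst$y, dimnames = list(rownames(inst$X), "s1"))
    fit <- fit_proportions(Y, inst$X, enet_config(lam = 1, alpha = 0, tol = 1e-10))
    closed <- solve(crossprod(inst$X) + diag(1 / 2, ncol(inst$X)),
                    crossprod(inst$X, inst$y))
    expect_lt(max(abs(fit[, 1] - closed)), 1e-5)
  }
})

test_that("full L1 shrinkage at huge lambda zeroes the solution", {
  inst <- random_enet_instance(seed = 3)
  Y <- matrix(inst$y, dimnames = list(rownames(inst$X), "s1"))
  fit <- fit_proportions(Y, inst$X, enet_config(lam = 1e9, alpha = 1))
  expect_equal(unname(fit[, 1]), rep(0, ncol(inst$X)))
})

test_that("solver objective matches the proximal-gradient oracle and beats random candidates", {
  set.seed(99)
  for (s in 1:5) {
    inst <- random_enet_instance(seed = 100 + s)
    Y <- matrix(inst$y, dimnames = list(rownames(inst$X), "s1"))
    fit <- fit_proportions(Y, inst$X, enet_config(lam = 1, alpha = 0.05, tol = 1e-9))
    obj_cd <- enet_objective(inst$y, inst$X, fit[, 1], 1, 0.05)
    oracle <- enet_prox_reference(inst$y, inst$X, 1, 0.05)
    expect_lt(abs(obj_cd - oracle$objective) / abs(oracle$objective), 1e-4)
    cand <- matrix(rnorm(6 * 2000, sd = 0.5), 6) + fit[, 1]
    obj_rand <- apply(cand, 2, function(p) enet_objective(inst$y, inst$X, p, 1, 0.05))
    expect_true(all(obj_cd <= obj_rand + 1e-12))
  }
})

test_that("solver agrees with glmnet under the penalty-rescaling adapter", {
  skip_if_not_installed("glmnet")
  inst <- random_enet_instance(seed = 7)
  n <- nrow(inst$X)
  Y <- matrix(inst$y, dimnames = list(rownames(inst$X), "s1"))
  fit <- fit_proportions(Y, inst$X, enet_config(lam = 1, alpha = 0.05, tol = 1e-10))
  g <- glmnet::glmnet(inst$X, inst$y, alpha = 0.05, lambda = 1 / (2 * n),
                      standardize = FALSE, intercept = FALSE, thresh = 1e-14)
  b <- as.numeric(g$beta)
  expect_lt(max(abs(fit[, 1] - b)), 5e-3)
  # on the shared objective the two solutions are equivalent (glmnet's own
  # convergence slack dominates the coefficient difference)
  obj_cd <- enet_objective(inst$y, inst$X, fit[, 1], 1, 0.05)
  obj_gl <- enet_objective(inst$y, inst$X, b, 1, 0.05)
  expect_lt(abs(obj_cd - obj_gl) / obj_cd, 1e-4)
  expect_lte(obj_cd, obj_gl + 1e-10)
})

test_that("L1 norm of the fit shrinks monotonically in lambda at alpha = 1", {
  inst <- random_enet_instance(seed = 11)
  Y <- matrix(inst$y, dimnames = list(rownames(inst$X), "s1"))
  l1 <- vapply(c(0, 0.5, 1, 5, 20, 100, 1000), function(l) {
    sum(abs(fit_proportions(Y, inst$X, enet_config(lam = l, alpha = 1))))
  }, 0)
  expect_true(all(diff(l1) <= 1e-8))
})

test_that("default elastic net recovers planted proportions on noisy mixtures", {
  sim <- simulate_reference(n_cell_types = 6, n_genes = 2000, markers_per_type = 100,
                            marker_fc = 5, noise_sd = 0, seed = 31)
  set.seed(32)
  K <- 6
  P <- matrix(rgamma(K * 30, 1), K, 30,
              dimnames = list(colnames(sim$reference), sprintf("m%02d", 1:30)))
  P <- sweep(P, 2, colSums(P), "/")
  Y <- simulate_mixture(sim$reference, P, noise_sd = 0.1, seed = 33)
  mk <- select_markers(sim$reference)
  X <- build_signature(sim$reference, mk)
  fit <- fit_proportions(Y[rownames(X), ], X)
  r <- vapply(rownames(P), function(ct) cor(P[ct, ], fit[ct, ]), 0)
  expect_true(all(r >= 0.9))
})

test_that("fit_proportions enforces gene alignment", {
  inst <- random_enet_instance(seed = 5)
  Y <- matrix(inst$y, dimnames = list(rev(rownames(inst$X)), "s1"))
  expect_error(fit_proportions(Y, inst$X), "do not match")
})

test_that("zscore_vs_control applies hand-checkable group statistics", {
  scores <- matrix(c(1, 2, 3, 4), nrow = 1,
                   dimnames = list("Neu", c("c1", "c2", "c3", "t1")))
  meta <- data.frame(sample_id = c("c1", "c2", "c3", "t1"),
                     compound = c("veh", "veh", "veh", "x"), dose_group = "d",
                     time_h = 3, replicate = c(1, 2, 3, 1),
                     is_control = c(TRUE, TRUE, TRUE, FALSE),
                     control_group_key = "k")
  z <- zscore_vs_control(scores, meta)
  expect_equal(z["Neu", "t1"], 2)           # (4 - 2) / sd(1,2,3) = 2/1
  expect_equal(mean(z["Neu", c("c1", "c2", "c3")]), 0)  # control block centred
  expect_identical(attr(z, "scale_tag"), "zscore_vs_control")

  # treated value equal to the control mean maps to 0
  scores2 <- scores; scores2[1, "t1"] <- 2
  expect_equal(zscore_vs_control(scores2, meta)["Neu", "t1"], 0)

  meta1 <- meta[-2, ]; sc1 <- scores[, -2, drop = FALSE]
  expect_error(zscore_vs_control(sc1[, -1, drop = FALSE], meta1[-1, ]), "fewer than 2")
  sc0 <- scores; sc0[1, 1:3] <- 5
  expect_error(zscore_vs_control(sc0, meta), "zero control SD")
})

test_that("zscore_between_samples normalizes each feature to mean 0, sd 1", {
  expect_equal(unname(zscore_between_samples(c(a = 2, b = 4))),
               c(-1, 1) / sqrt(2), tolerance = 1e-12, ignore_attr = TRUE)
  m <- matrix(rnorm(20), 4, 5, dimnames = list(paste0("f", 1:4), paste0("s", 1:5)))
  z <- zscore_between_samples(m)
  expect_equal(unname(rowMeans(z)), rep(0, 4))
  expect_equal(unname(apply(z, 1, sd)), rep(1, 4))
  expect_error(zscore_between_samples(c(a = 1, b = 1)), "zero variance")
  expect_error(zscore_between_samples(c(a = 1)), ">= 2 samples")
})
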