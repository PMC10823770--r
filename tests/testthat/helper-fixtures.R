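# Small in-code fixtures shared across test files.

toy_expression <- function() {
  matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
         dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
}

# 5-gene, 3-type toy reference with hand-derivable marker structure
# (pseudocount 0): g1 is a type-1 marker (10 vs 2, 2 -> ratio 5), g2 fails
# the 1.5 threshold (3 vs 2.5 -> 1.2), g3 is a type-2 marker (9 vs 3, 1 ->
# ratio 3), g4 is a type-3 marker (12 vs 4, 2 -> ratio 3), g5 is flat.
toy_reference <- function() {
  matrix(c(10, 3,   3, 4, 7,
            2, 2.5, 9, 2, 7,
            2, 2,   1, 12, 7),
         nrow = 5,
         dimnames = list(paste0("g", 1:5), c("T1", "T2", "T3")))
}

random_enet_instance <- function(n = 50, k = 6, seed = 1) {
  set.seed(seed)
  X <- matrix(abs(rnorm(n * k, 5, 2)), n, k,
              dimnames = list(sprintf("g%03d", 1:n), paste0("CT", 1:k)))
  y <- as.numeric(X %*% runif(k) + rnorm(n, 0, 0.5))
  list(X = X, y = y)
}

small_study <- function(seed = 11, effect_scale = 3) {
  simulate_study(n_compounds = 8, n_clusters = 4, n_replicates = 3,
                 effect_scale = effect_scale, seed = seed,
                 reference = simulate_reference(n_genes = 600, markers_per_type = 30,
                                                seed = seed + 1))
}

ari <- function(a, b) mclust::adjustedRandIndex(a[names(b)], b)
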