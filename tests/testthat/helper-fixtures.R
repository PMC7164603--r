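# Fixtures are built in code; independent oracles live here so the tests can
# check implementations against brute-force re-derivations.

small_cohort <- function(n = 600, d = 20, seed = 11, ...) {
  generate_cohort(cohort_config(n_patients = n, n_drugs = d, seed = seed, ...))
}

# A linearly separable toy shard: label = 1 iff the first feature is 1.
separable_shard <- function(n = 200, d = 10, seed = 42) {
  set.seed(seed)
  X <- matrix(rbinom(n * d, 1, 0.5), n, d)
  new_client_shard <- getFromNamespace("new_client_shard", "loadaboost")
  new_client_shard(
    client_id = 1L, ids = seq_len(n), features = X,
    labels = X[, 1], n_local = n
  )
}

# Brute-force forward pass: per-example loops, no matrix algebra shared with
# the implementation.
oracle_forward <- function(weights, X) {
  out <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    a <- X[i, ]
    for (l in seq_along(weights)) {
      W <- weights[[l]]$W
      b <- weights[[l]]$b
      z <- numeric(ncol(W))
      for (j in seq_len(ncol(W))) {
        z[j] <- sum(a * W[, j]) + b[j]
      }
      a <- if (l < length(weights)) pmax(z, 0) else 1 / (1 + exp(-z))
    }
    out[i] <- a
  }
  out
}

# Epoch-by-epoch replay of the retraining prose: initial training of
# ceiling(E/2) epochs, then retraining rounds r = 1, 2, ... of
# max(ceiling(E/2) - r + 1, 1) epochs each, halting the moment the cumulative
# epoch count reaches floor(3E/2). Returns the per-retraining-round epoch
# grants actually executed by a client that never beats the median.
oracle_retrain_grants <- function(E) {
  half_up <- ceiling(E / 2)
  budget <- floor(3 * E / 2)
  total <- half_up
  grants <- integer()
  r <- 0L
  while (total < budget) {
    r <- r + 1L
    allowance <- max(half_up - r + 1, 1)
    ran <- 0L
    for (e in seq_len(allowance)) {
      total <- total + 1L
      ran <- ran + 1L
      if (total >= budget) break
    }
    grants <- c(grants, ran)
  }
  list(initial = half_up, grants = grants, budget = budget)
}

# Weights with a single 2-parameter-per-output layer, for hand arithmetic.
vector_weights <- function(v) {
  w <- list(list(W = matrix(v[1], 1, 1), b = v[2]))
  class(w) <- "fed_weights"
  w
}
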