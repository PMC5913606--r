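# Shared fixtures and independent oracles for the test suite.

# Literal double-loop sandwich oracle: w_j = sum_k e_k x_k accumulated
# element by element, nothing shared with the package implementation.
oracle_cluster_sandwich <- function(X, e, cluster, correction = FALSE) {
  p <- ncol(X)
  ids <- unique(cluster)
  meat <- matrix(0, p, p)
  for (j in ids) {
    w <- rep(0, p)
    for (k in which(cluster == j)) {
      w <- w + e[k] * X[k, ]
    }
    meat <- meat + outer(w, w)
  }
  if (correction) meat <- meat * length(ids) / (length(ids) - 1)
  bread <- solve(t(X) %*% X)
  bread %*% meat %*% bread
}

# HC0 heteroskedasticity-robust sandwich, written independently.
oracle_hc0 <- function(X, e) {
  bread <- solve(t(X) %*% X)
  meat <- t(X) %*% diag(e^2) %*% X
  bread %*% meat %*% bread
}

# Minimal well-formed dataset: 2 CpGs x 4 observations (2 individuals x 2 ages).
tiny_dataset <- function() {
  beta <- matrix(c(0.2, 0.3, 0.25, 0.35,
                   0.6, 0.55, 0.65, 0.5), nrow = 2, byrow = TRUE,
                 dimnames = list(c("cgA", "cgB"),
                                 c("s1_t1", "s1_t2", "s2_t1", "s2_t2")))
  samples <- data.frame(
    observation_id = c("s1_t1", "s1_t2", "s2_t1", "s2_t2"),
    individual_id = c("s1", "s1", "s2", "s2"),
    age = c(10, 12, 10, 12),
    exposure = c(0, 0, 1, 1),
    stringsAsFactors = FALSE
  )
  longitudinal_dataset(beta, samples)
}

# Random clustered regression instance for oracle comparisons.
random_instance <- function(m, n_per, p, seed) {
  set.seed(seed)
  n <- m * n_per
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1)))
  cluster <- rep(seq_len(m), each = n_per)
  y <- X %*% rnorm(p) + rnorm(n) + rep(rnorm(m), each = n_per)
  list(X = X, y = as.numeric(y), cluster = cluster)
}

# Small simulated study, defaults scaled down for unit tests.
small_sim_config <- function(n_individuals = 120, n_cpgs = 20,
                             n_causal = min(6, n_cpgs), seed = 7, ...) {
  simulation_config(n_individuals = n_individuals, n_cpgs = n_cpgs,
                    n_causal = n_causal, seed = seed, ...)
}
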