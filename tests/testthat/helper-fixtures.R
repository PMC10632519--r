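# small cohort used across tests: 8 fully observable modules, 60 patients
small_cohort <- function(seed = 1, ...) {
  generate_cohort(cohort_config(n_patients = 60, n_genes = 400,
                                n_modules = 8, module_sizes = rep(40L, 8),
                                seed = seed, ...))
}

# random named count matrix for I/O round trips
random_counts <- function(ng = 12, ns = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(ng * ns, 30), ng, ns,
              dimnames = list(sprintf("g%02d", 1:ng), sprintf("s%02d", 1:ns)))
  storage.mode(m) <- "integer"
  m
}

# binary-outcome design for classifier tests
logit_data <- function(n = 60, p = 8, beta = c(1, -0.8), seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  X <- scale(X)
  X <- sweep(X, 2, apply(X, 2, sd), "/")
  eta <- X[, seq_along(beta), drop = FALSE] %*% beta
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  list(X = X, y = y)
}
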