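#' Mixing-parameter grid for the inner cross-validation
#'
#' `a_n = (n/20)^2` for `n = 0, ..., 20`: 21 values concentrated toward the
#' ridge end, with endpoints 0 (ridge) and 1 (lasso).
#'
#' @return Numeric vector of length 21.
#' @export
alpha_grid <- function() (0:20 / 20)^2

# internal: penalized negative binomial log-likelihood of Eq-style loss
enet_objective <- function(X, y, b0, beta, alpha, lam) {
  eta <- drop(b0 + X %*% beta)
  nll <- mean(log1p(exp(eta)) - y * eta)
  nll + lam * ((1 - alpha) * sum(beta^2) / 2 + alpha * sum(abs(beta)))
}

#' Elastic-net logistic regression fit
#'
#' Minimizes the penalized negative binomial log-likelihood
#' `(1/N) sum_i -log L(y_i, b0 + x_i'beta) +
#'  lambda [(1-alpha) ||beta||_2^2 / 2 + alpha ||beta||_1]`
#' by cyclic coordinate descent on the IRLS quadratic approximation with
#' soft-thresholding. The intercept is unpenalized. Convergence when the
#' largest coefficient change in a sweep falls below 1e-7.
#'
#' @param X Standardized samples x features matrix.
#' @param y Binary 0/1 outcome vector (both classes required).
#' @param alpha Mixing parameter in \[0, 1\] (1 = lasso).
#' @param lam Penalty strength >= 0.
#' @param tol Convergence tolerance on coefficient changes.
#' @param max_sweeps Sweep budget before a non-convergence error.
#' @return List of class `enet_model`: `intercept`, `coefficients` (named),
#'   `alpha`, `lam`, `objective`.
#' @export
enet_fit <- function(X, y, alpha, lam, tol = 1e-7, max_sweeps = 1e5) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2) stop("y must contain both classes")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (lam < 0) stop("lam must be >= 0")
  fit <- enet_path_cpp(X, as.numeric(y), alpha, lam, tol,
                       as.integer(max_sweeps))
  if (!fit$converged[1])
    stop("coordinate descent did not converge in ", max_sweeps,
         " sweeps (alpha=", alpha, ", lambda=", lam, ")")
  beta <- drop(fit$betas)
  names(beta) <- colnames(X)
  structure(list(
    intercept = fit$intercepts[1],
    coefficients = beta,
    alpha = alpha, lam = lam,
    objective = enet_objective(X, y, fit$intercepts[1], beta, alpha, lam)),
    class = "enet_model")
}

#' Predicted probabilities from an elastic-net model
#'
#' @param object An `enet_model`.
#' @param newx Samples x features matrix on the model's (standardized) scale.
#' @param ... Unused.
#' @return Probabilities in (0, 1).
#' @export
predict.enet_model <- function(object, newx, ...) {
  eta <- drop(object$intercept + as.matrix(newx) %*% object$coefficients)
  p <- 1 / (1 + exp(-eta))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Penalty-strength path
#'
#' `lambda_max = max_j |sum_i x_ij (y_i - ybar)| / (N alpha)` (the smallest
#' penalty with an all-zero solution), log-spaced down to
#' `lambda_max * ratio` over `n_lambda` values. For `alpha = 0` the maximum
#' is computed with the surrogate `alpha = 0.001`, the standard convention
#' for a finite ridge path start.
#'
#' @param X Standardized samples x features matrix.
#' @param y Binary outcome.
#' @param alpha Mixing parameter.
#' @param n_lambda Path length (default 100).
#' @param ratio Smallest/largest lambda (default 1e-2).
#' @return Strictly decreasing numeric vector of length `n_lambda`.
#' @export
lambda_path <- function(X, y, alpha, n_lambda = 100, ratio = 1e-2) {
  if (length(unique(y)) < 2) stop("y must contain both classes")
  a <- max(alpha, 0.001)
  n <- length(y)
  lmax <- max(abs(crossprod(as.matrix(X), y - mean(y)))) / (n * a)
  exp(seq(log(lmax), log(lmax * ratio), length.out = n_lambda))
}

# internal: stratified fold assignment (both classes spread across folds)
stratified_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

#' Inner cross-validation over the (alpha, lambda) grid
#'
#' Grid search over `alpha_grid` x per-alpha [lambda_path()]; the error is
#' the mean out-of-fold binomial deviance
#' `-2 mean[y log p + (1-y) log(1-p)]` with probabilities clipped to
#' `[1e-12, 1-1e-12]`. Folds are stratified. Ties are resolved toward the
#' larger lambda, then the smaller alpha.
#'
#' @param X Standardized samples x features matrix.
#' @param y Binary outcome.
#' @param alphas Mixing-parameter grid (default [alpha_grid()]).
#' @param n_folds Number of folds (reduced with a warning if n is smaller).
#' @param n_lambda Path length per alpha.
#' @param seed Seed for the fold draw.
#' @return List: `best_alpha`, `best_lambda`, `cv_error` (the attained
#'   minimum), `surface` (long data.frame alpha/lambda/error).
#' @export
inner_cv <- function(X, y, alphas = alpha_grid(), n_folds = 10,
                     n_lambda = 100, seed = 0L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("y must contain both classes")
  n <- length(y)
  if (n < n_folds) {
    warning("reducing folds from ", n_folds, " to ", n)
    n_folds <- n
  }
  set.seed(seed)
  folds <- stratified_folds(y, n_folds)
  surface <- list()
  for (a in alphas) {
    lams <- lambda_path(X, y, a, n_lambda = n_lambda)
    dev_sum <- matrix(0, 1, length(lams))
    pred <- matrix(NA_real_, n, length(lams))
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2) next
      # path tolerance: out-of-fold deviance is insensitive below 1e-3
      # (final refits use the tight enet_fit tolerance); the sweep cap
      # bounds worst-case cost on strongly correlated designs
      fit <- enet_path_cpp(X[tr, , drop = FALSE], y[tr], a, lams,
                           1e-3, 2000L)
      eta <- sweep(X[!tr, , drop = FALSE] %*% fit$betas, 2,
                   fit$intercepts, "+")
      pred[!tr, ] <- 1 / (1 + exp(-eta))
    }
    pred <- pmin(pmax(pred, 1e-12), 1 - 1e-12)
    err <- vapply(seq_along(lams), function(l) {
      ok <- !is.na(pred[, l])
      -2 * mean(y[ok] * log(pred[ok, l]) +
                  (1 - y[ok]) * log(1 - pred[ok, l]))
    }, 0)
    surface[[length(surface) + 1L]] <-
      data.frame(alpha = a, lambda = lams, error = err)
  }
  surface <- do.call(rbind, surface)
  # ties -> larger lambda, then smaller alpha
  ord <- order(surface$error, -surface$lambda, surface$alpha)
  best <- surface[ord[1], ]
  list(best_alpha = best$alpha, best_lambda = best$lambda,
       cv_error = best$error, surface = surface)
}

#' Nested cross-validation recurrence classifier
#'
#' Outer stratified folds give an unbiased performance estimate; inside each
#' outer training split the most variable genes (by MAD) are selected,
#' features are standardized with training statistics only, the
#' (alpha, lambda) pair is chosen by [inner_cv()], the model is refit on the
#' full training split and applied to the held-out samples. Out-of-fold
#' predicted probabilities are pooled over all folds, covering every labeled
#' sample exactly once.
#'
#' @param expr Gene x sample transformed expression matrix.
#' @param labels Named binary vector (sample -> 0/1); samples with NA are
#'   dropped.
#' @param outer_folds Number of outer folds (default 10).
#' @param top_n Genes selected per fold by MAD on training samples only.
#' @param alphas Mixing grid for the inner search.
#' @param inner_folds,n_lambda Inner-search settings.
#' @param seed Seed controlling all fold draws.
#' @return List of class `cv_prediction`: `prob` (named pooled out-of-fold
#'   probabilities), `y`, `fold`, `chosen` (per-fold alpha/lambda), `seed`.
#' @export
nested_cv <- function(expr, labels, outer_folds = 10, top_n = 200,
                      alphas = alpha_grid(), inner_folds = 10,
                      n_lambda = 100, seed = 0L) {
  labels <- labels[!is.na(labels)]
  # canonical sample order: fold draws must not depend on column order
  samples <- sort(intersect(colnames(expr), names(labels)))
  if (!length(samples)) stop("no labeled samples found in expr")
  y <- as.numeric(labels[samples])
  if (length(unique(y)) < 2) stop("labels must contain both classes")
  set.seed(seed)
  # stratified outer folds; re-draw (bounded) if a training split loses a class
  for (attempt in 1:100) {
    folds <- stratified_folds(y, outer_folds)
    ok <- all(vapply(seq_len(outer_folds), function(f)
      length(unique(y[folds != f])) == 2 && sum(folds == f) > 0, TRUE))
    if (ok) break
    if (attempt == 100) stop("could not draw valid stratified outer folds")
  }
  prob <- rep(NA_real_, length(y))
  names(prob) <- samples
  chosen <- data.frame(fold = seq_len(outer_folds), alpha = NA_real_,
                       lambda = NA_real_)
  for (f in seq_len(outer_folds)) {
    tr <- folds != f
    tr_samples <- samples[tr]
    genes <- select_variable_genes(expr[, tr_samples, drop = FALSE],
                                   top_n, method = "mad")
    Xtr <- t(expr[genes, tr_samples, drop = FALSE])
    mu <- colMeans(Xtr)
    sdev <- apply(Xtr, 2, sd)
    sdev[sdev == 0] <- 1
    Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdev, "/")
    cv <- inner_cv(Xtr, y[tr], alphas = alphas, n_folds = inner_folds,
                   n_lambda = n_lambda, seed = seed + f)
    fit <- enet_fit(Xtr, y[tr], cv$best_alpha, cv$best_lambda)
    Xte <- t(expr[genes, samples[!tr], drop = FALSE])
    Xte <- sweep(sweep(Xte, 2, mu), 2, sdev, "/")
    prob[!tr] <- predict(fit, Xte)
    chosen$alpha[f] <- cv$best_alpha
    chosen$lambda[f] <- cv$best_lambda
  }
  structure(list(prob = prob, y = setNames(y, samples), fold = folds,
                 chosen = chosen, seed = seed), class = "cv_prediction")
}
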