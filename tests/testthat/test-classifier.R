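# independent Newton-Raphson for unpenalized logistic regression
newton_logistic <- function(X, y, iter = 200) {
  Xi <- cbind(1, X)
  b <- numeric(ncol(Xi))
  for (i in seq_len(iter)) {
    p <- 1 / (1 + exp(-drop(Xi %*% b)))
    W <- p * (1 - p)
    step <- solve(crossprod(Xi, Xi * W), crossprod(Xi, y - p))
    b <- b + drop(step)
    if (max(abs(step)) < 1e-12) break
  }
  b
}

test_that("the alpha grid follows the quadratic spacing", {
  a <- alpha_grid()
  expect_length(unique(a), 21)
  expect_equal(a[1], 0)
  expect_equal(a[21], 1)
  expect_equal(a[11], 0.25)
})

test_that("the penalty threshold and null fits behave as defined", {
  d <- logit_data(n = 50, p = 6, seed = 2)
  lp <- lambda_path(d$X, d$y, alpha = 1)
  expect_length(lp, 100)
  expect_true(all(diff(lp) < 0))
  fit <- enet_fit(d$X, d$y, 1, lp[1])
  expect_true(all(fit$coefficients == 0))
  expect_equal(fit$intercept, log(mean(d$y) / (1 - mean(d$y))),
               tolerance = 1e-6)
  # hand-computed lambda_max on a tiny design
  Xh <- matrix(c(1, -1, 2, 0, 0.5, 1.5, -0.5, 0.5), 4, 2)
  yh <- c(1, 0, 1, 0)
  expect_equal(lambda_path(Xh, yh, 0.5, n_lambda = 3)[1],
               max(abs(crossprod(Xh, yh - mean(yh)))) / (4 * 0.5))
})

test_that("the unpenalized fit matches a Newton oracle", {
  d <- logit_data(n = 40, p = 3, beta = c(0.7, -0.5, 0.2), seed = 3)
  fit <- enet_fit(d$X, d$y, 0.5, 0, tol = 1e-9)
  oracle <- newton_logistic(d$X, d$y)
  expect_lt(max(abs(c(fit$intercept, fit$coefficients) - oracle)), 1e-5)
})

test_that("the solution minimizes the penalized objective (convex oracle)", {
  # split beta = b+ - b- makes the L1 term smooth under box constraints,
  # so a generic bounded quasi-Newton optimizer can solve the same problem
  for (s in 1:5) {
    set.seed(s)
    n <- 20; p <- 5
    X <- scale(matrix(rnorm(n * p), n, p))
    X <- sweep(X, 2, apply(X, 2, sd), "/")
    colnames(X) <- paste0("f", 1:p)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    alpha <- 0.5; lam <- 0.1
    fit <- enet_fit(X, y, alpha, lam)
    obj_split <- function(par) {
      b0 <- par[1]; bp <- par[2:(p + 1)]; bn <- par[(p + 2):(2 * p + 1)]
      b <- bp - bn
      eta <- b0 + drop(X %*% b)
      mean(log1p(exp(eta)) - y * eta) +
        lam * ((1 - alpha) * sum(b^2) / 2 + alpha * sum(bp + bn))
    }
    opt <- optim(rep(0, 2 * p + 1), obj_split, method = "L-BFGS-B",
                 lower = c(-Inf, rep(0, 2 * p)),
                 control = list(maxit = 2000, factr = 1e3))
    expect_lt(fit$objective, opt$value + 1e-6)
    expect_gt(fit$objective, opt$value - 1e-6)
  }
})

test_that("warm-started path solutions vary continuously in lambda", {
  d <- logit_data(n = 60, p = 10, beta = c(1.5, -1), seed = 4)
  lams <- lambda_path(d$X, d$y, 0.5, n_lambda = 60)
  fits <- lapply(lams, function(l) enet_fit(d$X, d$y, 0.5, l))
  B <- vapply(fits, function(f) f$coefficients, numeric(10))
  objs <- vapply(fits, function(f) f$objective, 0)
  steps <- apply(abs(B[, -1, drop = FALSE] - B[, -ncol(B), drop = FALSE]),
                 2, max)
  expect_lt(max(steps), 0.25)  # no jumps along a fine path
  # each solution beats the all-zero vector for its own objective
  for (i in c(1, 30, 60)) {
    f <- fits[[i]]
    null_obj <- mean(log1p(exp(f$intercept)) - d$y * f$intercept)
    expect_lte(f$objective, null_obj + 1e-10)
  }
  expect_error(enet_fit(d$X, rep(1, 60), 0.5, 0.1), "both classes")
})

test_that("the inner CV search attains the minimum of its own error surface", {
  d <- logit_data(n = 50, p = 6, seed = 5)
  # degenerate grid: single pair is returned untouched
  lam1 <- lambda_path(d$X, d$y, 0.5, n_lambda = 1)
  one <- inner_cv(d$X, d$y, alphas = 0.5, n_folds = 5, n_lambda = 1,
                  seed = 1)
  expect_equal(one$best_alpha, 0.5)
  expect_equal(one$best_lambda, lam1[1])
  cv <- inner_cv(d$X, d$y, alphas = c(0.1, 0.5, 1), n_folds = 5,
                 n_lambda = 12, seed = 2)
  expect_equal(cv$cv_error, min(cv$surface$error))
  hit <- cv$surface[cv$surface$alpha == cv$best_alpha &
                      cv$surface$lambda == cv$best_lambda, ]
  expect_equal(hit$error, cv$cv_error)
  # tie-break goes to the larger lambda at equal error
  surf <- cv$surface
  ties <- surf[surf$error == min(surf$error), ]
  expect_equal(cv$best_lambda, max(ties$lambda))
})

test_that("nested CV is reproducible and invariant to sample order", {
  co <- small_cohort(seed = 6)
  expr <- vst_transform(co$counts_normal)
  lab <- derive_outcome_labels(co$metadata)
  rec <- setNames(ifelse(lab$recurrence_5yr == "positive", 1,
                         ifelse(lab$recurrence_5yr == "negative", 0, NA)),
                  paste0(lab$patient_id, "_N"))
  run <- function(e, l) nested_cv(e, l, outer_folds = 4, top_n = 40,
                                  alphas = c(0.25, 1), inner_folds = 4,
                                  n_lambda = 15, seed = 3)
  cv1 <- run(expr, rec)
  cv2 <- run(expr, rec)
  expect_identical(cv1$prob, cv2$prob)
  expect_true(all(!is.na(cv1$prob)))
  expect_true(all(cv1$prob > 0 & cv1$prob < 1))
  set.seed(9)
  perm <- sample(ncol(expr))
  cv3 <- run(expr[, perm], rec)
  expect_equal(roc_auc(cv3$prob, cv3$y)$auc,
               roc_auc(cv1$prob, cv1$y)$auc)
  expect_error(nested_cv(expr, setNames(rep(1, 10),
                                        colnames(expr)[1:10])),
               "both classes")
})

test_that("ROC analysis matches brute-force pair counting", {
  # perfect separation
  r <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(r$ci_high, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  # all tied scores
  expect_equal(roc_auc(rep(0.5, 8), rep(c(0, 1), 4))$auc, 0.5)
  # pair-counting oracle, with ties
  set.seed(12)
  score <- sample(seq(0, 1, 0.1), 15, replace = TRUE)
  y <- rbinom(15, 1, 0.5); y[1:2] <- c(0, 1)
  r2 <- roc_auc(score, y)
  pos <- score[y == 1]; neg <- score[y == 0]
  pairs <- expand.grid(p = pos, n = neg)
  oracle <- mean((pairs$p > pairs$n) + 0.5 * (pairs$p == pairs$n))
  expect_equal(r2$auc, oracle, tolerance = 1e-12)
  expect_true(all(diff(r2$curve$fpr) >= 0) && all(diff(r2$curve$tpr) >= 0))
  # complement symmetry on tie-free predictions
  sf <- seq(0.05, 0.95, length.out = 14)
  yf <- rep(c(0, 1), 7)
  expect_equal(roc_auc(sf, yf)$auc + roc_auc(-sf, yf)$auc, 1)
})

test_that("the paired DeLong test agrees with an independent implementation", {
  set.seed(13)
  y <- rbinom(30, 1, 0.5); y[1:2] <- c(0, 1)
  pa <- runif(30) + 0.5 * y
  pb <- runif(30) + 0.2 * y
  same <- delong_test(pa, pa, y)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  dl <- delong_test(pa, pb, y)
  expect_equal(sign(dl$z), sign(dl$auc_a - dl$auc_b))
  skip_if_not_installed("pROC")
  ref <- pROC::roc.test(pROC::roc(y, pa, quiet = TRUE),
                        pROC::roc(y, pb, quiet = TRUE), method = "delong")
  expect_equal(dl$p_value, unname(ref$p.value), tolerance = 1e-8)
  # single-predictor DeLong variance against pROC's
  r <- roc_auc(pa, y)
  ref_ci <- pROC::ci.auc(pROC::roc(y, pa, quiet = TRUE), method = "delong")
  expect_equal(r$ci_low, max(0, ref_ci[1]), tolerance = 1e-8)
  expect_equal(r$ci_high, min(1, ref_ci[3]), tolerance = 1e-8)
})

test_that("risk stratification splits at the median with ties going high", {
  set.seed(14)
  p123 <- runif(123)
  g <- stratify_risk(p123)
  expect_equal(sum(g == "high"), 62)
  expect_equal(sum(g == "low"), 61)
  expect_equal(unname(stratify_risk(c(0.1, 0.2, 0.3, 0.4))),
               c("low", "low", "high", "high"))
  expect_warning(gt <- stratify_risk(rep(0.5, 6)), "tied")
  expect_true(all(gt == "high"))
})

test_that("fits agree with an independent elastic-net implementation", {
  skip_if_not_installed("glmnet")
  d <- logit_data(n = 70, p = 12, beta = c(1, -0.8, 0.5), seed = 6)
  for (a in c(0.3, 1)) for (lam in c(0.02, 0.1)) {
    fit <- enet_fit(d$X, d$y, a, lam)
    ref <- glmnet::glmnet(d$X, d$y, family = "binomial", alpha = a,
                          lambda = lam, standardize = FALSE, thresh = 1e-12)
    expect_lt(max(abs(fit$coefficients - as.numeric(ref$beta))), 1e-5)
    expect_lt(abs(fit$intercept - as.numeric(ref$a0)), 1e-5)
  }
})
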