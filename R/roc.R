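# placement values: for each positive, the fraction of negatives it beats
# (ties count 1/2), and symmetrically for negatives
placements <- function(score, y) {
  pos <- score[y == 1]
  neg <- score[y == 0]
  v10 <- vapply(pos, function(s)
    mean((s > neg) + 0.5 * (s == neg)), 0)
  v01 <- vapply(neg, function(s)
    mean((pos > s) + 0.5 * (pos == s)), 0)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' ROC curve, AUC and DeLong confidence interval
#'
#' AUC by the trapezoidal rule over the empirical ROC, equal to the
#' tie-corrected Mann-Whitney statistic. The 95% CI uses the DeLong
#' placement-value variance. The reported operating point maximizes
#' Youden's J.
#'
#' @param score Numeric predictions (higher = more likely positive).
#' @param y Binary 0/1 labels.
#' @return List of class `roc_result`: `auc`, `ci_low`, `ci_high`, `curve`
#'   (data.frame threshold/fpr/tpr), `sensitivity`, `specificity`,
#'   `threshold` (Youden point).
#' @export
roc_auc <- function(score, y) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("both classes required")
  pl <- placements(score, y)
  auc <- pl$auc
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  v <- var(pl$v10) / n1 + var(pl$v01) / n0
  half <- qnorm(0.975) * sqrt(v)
  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  curve <- do.call(rbind, lapply(thr, function(t) {
    data.frame(threshold = t,
               fpr = mean(score[y == 0] >= t),
               tpr = mean(score[y == 1] >= t))
  }))
  j <- curve$tpr - curve$fpr
  best <- which.max(j)
  structure(list(auc = auc,
                 ci_low = max(0, auc - half), ci_high = min(1, auc + half),
                 curve = curve,
                 sensitivity = curve$tpr[best],
                 specificity = 1 - curve$fpr[best],
                 threshold = curve$threshold[best]),
            class = "roc_result")
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two prediction vectors on the same samples via
#' placement values: `z = (auc_a - auc_b) / sqrt(var_a + var_b - 2 cov)`,
#' two-sided normal p. A zero-variance difference with equal AUCs returns
#' p = 1.
#'
#' @param pred_a,pred_b Prediction vectors on identical samples.
#' @param y Binary 0/1 labels.
#' @return List: `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
delong_test <- function(pred_a, pred_b, y) {
  stopifnot(length(pred_a) == length(pred_b), length(pred_a) == length(y))
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("both classes required")
  pa <- placements(pred_a, y)
  pb <- placements(pred_b, y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  s10 <- cov(cbind(pa$v10, pb$v10))
  s01 <- cov(cbind(pa$v01, pb$v01))
  vd <- s10[1, 1] / n1 + s01[1, 1] / n0 +
    s10[2, 2] / n1 + s01[2, 2] / n0 -
    2 * (s10[1, 2] / n1 + s01[1, 2] / n0)
  d <- pa$auc - pb$auc
  if (vd <= 0) {
    z <- if (d == 0) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(vd)
  }
  list(auc_a = pa$auc, auc_b = pb$auc, z = z,
       p_value = if (is.infinite(z)) 0 else 2 * pnorm(-abs(z)))
}

#' Median split of predicted risk
#'
#' High/low risk by the median of the pooled predicted probabilities; ties
#' at the median go to the high group, so with odd n the high group gets the
#' extra sample (123 distinct values give 62 high / 61 low).
#'
#' @param prob Numeric predictions (a `cv_prediction` is also accepted).
#' @return Character vector `"high"`/`"low"`, named like the input.
#' @export
stratify_risk <- function(prob) {
  if (inherits(prob, "cv_prediction")) prob <- prob$prob
  med <- median(prob)
  grp <- ifelse(prob >= med, "high", "low")
  if (all(grp == "high"))
    warning("all predictions tied at the median; everyone is high risk")
  setNames(grp, names(prob))
}
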