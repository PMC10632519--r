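#' Kaplan-Meier estimate
#'
#' Product-limit estimator with Greenwood variance and log-log 95%
#' confidence bands.
#'
#' @param time Positive event/censoring times (days).
#' @param event 0/1 event indicators.
#' @return List of class `km_curve`: `time` (event times), `surv`,
#'   `n_risk`, `n_event`, `greenwood_var`, `ci_low`, `ci_high`.
#' @export
km_estimate <- function(time, event) {
  if (any(time <= 0)) stop("times must be positive")
  stopifnot(length(time) == length(event), all(event %in% c(0, 1)))
  fit <- survfit(Surv(time, event) ~ 1, conf.type = "log-log")
  # survfit std.err is the SE of log S(t); Greenwood var of S is (S * se)^2,
  # taken as 0 once the curve reaches S = 0
  gv <- (fit$surv * fit$std.err)^2
  gv[fit$surv == 0] <- 0
  structure(list(time = fit$time, surv = fit$surv,
                 n_risk = fit$n.risk, n_event = fit$n.event,
                 greenwood_var = gv,
                 ci_low = fit$lower, ci_high = fit$upper),
            class = "km_curve")
}

#' Log-rank test
#'
#' Standard k-group log-rank with hypergeometric variance; p from the
#' chi-square distribution with k - 1 degrees of freedom.
#'
#' @param time,event Survival records.
#' @param group Group labels (>= 2 non-empty groups).
#' @return List: `chisq`, `df`, `p_value`, `obs`, `exp` (per group).
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) < 2) stop("need at least 2 non-empty groups")
  sd_ <- survdiff(Surv(time, event) ~ group)
  df <- nlevels(group) - 1
  p <- pchisq(sd_$chisq, df, lower.tail = FALSE)
  list(chisq = unname(sd_$chisq), df = df, p_value = p,
       obs = sd_$obs, exp = sd_$exp)
}

#' Multivariate outcome model (Cox or logistic)
#'
#' `cox`: proportional-hazards partial likelihood, Newton-Raphson with Efron
#' tie handling; `logistic`: unpenalized binomial GLM. Wald standard errors
#' and p-values come from the inverse information; separation or
#' non-convergence is an error with diagnostics.
#'
#' @param outcome For `cox`, a data.frame/list with `time` and `event`; for
#'   `logistic`, a binary vector.
#' @param covariates data.frame of covariates (complete cases required).
#' @param model `"cox"` (default, for time-to-event input) or `"logistic"`.
#' @return data.frame per covariate: coef, se, ci_low, ci_high, p_value
#'   (Wald); attribute `model`.
#' @export
multivariate_fit <- function(outcome, covariates, model = c("cox", "logistic")) {
  model <- match.arg(model)
  covariates <- as.data.frame(covariates)
  if (anyNA(covariates)) stop("covariates must be complete")
  if (model == "cox") {
    d <- cbind(data.frame(.time = outcome$time, .event = outcome$event),
               covariates)
    fit <- coxph(Surv(.time, .event) ~ ., data = d, ties = "efron")
    if (!is.null(fit$info) && isTRUE(fit$info > 0))
      stop("Cox model did not converge")
    est <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
  } else {
    d <- cbind(data.frame(.y = as.numeric(outcome)), covariates)
    fit <- glm(.y ~ ., data = d, family = binomial())
    if (!fit$converged) stop("logistic model did not converge")
    est <- coef(fit)[-1]
    se <- sqrt(diag(vcov(fit)))[-1]
  }
  if (any(!is.finite(se)) || any(se > 1e3))
    stop("unstable fit (possible separation): max SE = ",
         format(max(se), digits = 3))
  data.frame(term = names(est), coef = unname(est), se = unname(se),
             ci_low = unname(est - 1.96 * se),
             ci_high = unname(est + 1.96 * se),
             p_value = unname(2 * pnorm(-abs(est / se))),
             stringsAsFactors = FALSE)
}

#' Harrell's concordance index (higher score = worse outcome)
#'
#' Fraction of usable pairs (the member with the shorter time has an event)
#' in which the higher score goes with the shorter survival; score ties
#' count 1/2. Values above 0.5 therefore mean high scores are associated
#' with worse survival.
#'
#' @param score Risk score aligned to the records.
#' @param time,event Survival records.
#' @return Concordance in \[0, 1\].
#' @export
c_index <- function(score, time, event) {
  n <- length(score)
  stopifnot(length(time) == n, length(event) == n)
  concordant <- 0
  usable <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) next
      shorter <- if (time[i] < time[j]) i else j
      longer <- if (shorter == i) j else i
      if (event[shorter] != 1) next
      usable <- usable + 1
      if (score[shorter] > score[longer]) concordant <- concordant + 1
      else if (score[shorter] == score[longer])
        concordant <- concordant + 0.5
    }
  }
  if (usable == 0) stop("no usable pairs")
  concordant / usable
}

#' Association map of module scores with patient variables
#'
#' Continuous variables: Pearson correlation with its t-test p. Binary
#' variables: Pearson on 0/1 coding (point-biserial). Ordinal variables:
#' Spearman with the t approximation. Constant variables are recorded as NA
#' with a warning.
#'
#' @param scores Samples x modules score matrix (rownames = sample IDs).
#' @param meta Sample metadata (rownames or `sample_id` matching scores).
#' @param variables Named character vector: variable -> type
#'   (`"continuous"`, `"binary"`, `"ordinal"`).
#' @return Long data.frame: module, variable, method, estimate, p_value,
#'   sign.
#' @export
associate_scores <- function(scores, meta, variables) {
  ids <- if ("sample_id" %in% names(meta)) meta$sample_id else rownames(meta)
  m <- meta[match(rownames(scores), ids), , drop = FALSE]
  rows <- list()
  for (v in names(variables)) {
    type <- variables[[v]]
    x <- m[[v]]
    x <- switch(type,
                continuous = as.numeric(x),
                binary = as.numeric(as.factor(x)) - 1,
                ordinal = as.numeric(x),
                stop("unknown variable type: ", type))
    for (mod in colnames(scores)) {
      s <- scores[, mod]
      if (length(unique(x[!is.na(x)])) < 2) {
        warning("constant variable '", v, "'; recorded as NA")
        est <- NA_real_; p <- NA_real_
        method <- if (type == "ordinal") "spearman" else "pearson"
      } else if (type == "ordinal") {
        ct <- suppressWarnings(cor.test(s, x, method = "spearman",
                                        exact = FALSE))
        est <- unname(ct$estimate); p <- ct$p.value; method <- "spearman"
      } else {
        ct <- cor.test(s, x, method = "pearson")
        est <- unname(ct$estimate); p <- ct$p.value; method <- "pearson"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        module = mod, variable = v, method = method, estimate = est,
        p_value = p,
        sign = ifelse(is.na(est), NA, ifelse(est >= 0, "positive",
                                             "negative")),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
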