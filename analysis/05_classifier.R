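#!/usr/bin/env Rscript
# Nested-CV elastic-net classification of 5-year recurrence from TAN
# expression, with pooled out-of-fold ROC, a tumor-tissue comparison model,
# DeLong test between the two, and median-split risk groups.

library(tanprog)

out <- "results/classifier"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
expr <- readRDS("results/preprocess/expr.rds")
meta <- read.csv("results/cohort/metadata.csv")
labels <- read.csv("results/preprocess/labels.csv")

rec <- setNames(
  ifelse(labels$recurrence_5yr == "positive", 1,
         ifelse(labels$recurrence_5yr == "negative", 0, NA)),
  labels$patient_id)

run_tissue <- function(tissue_code) {
  ids <- meta$sample_id[meta$tissue == tissue_code]
  lab <- setNames(rec[sub("_[TN]$", "", ids)], ids)
  nested_cv(expr[, ids], lab, seed = 1)
}

cv_tan <- run_tissue("normal")
cv_tum <- run_tissue("tumor")
roc_tan <- roc_auc(cv_tan$prob, cv_tan$y)
roc_tum <- roc_auc(cv_tum$prob, cv_tum$y)
cat(sprintf("TAN model AUC %.3f [%.3f, %.3f]; tumor model AUC %.3f\n",
            roc_tan$auc, roc_tan$ci_low, roc_tan$ci_high, roc_tum$auc))

# the two models predict the same patients in the same order
stopifnot(identical(sub("_N$", "", names(cv_tan$prob)),
                    sub("_T$", "", names(cv_tum$prob))))
dl <- delong_test(cv_tan$prob, cv_tum$prob, cv_tan$y)
cat(sprintf("DeLong TAN vs tumor: z = %.2f, p = %.4g\n", dl$z, dl$p_value))

risk <- stratify_risk(cv_tan)
preds <- data.frame(sample_id = names(cv_tan$prob), prob = cv_tan$prob,
                    y = cv_tan$y, risk = risk)
write.csv(preds, file.path(out, "cv_predictions_tan.csv"),
          row.names = FALSE)
write.csv(roc_tan$curve, file.path(out, "roc_tan.csv"), row.names = FALSE)
write.csv(data.frame(model = c("tan", "tumor"),
                     auc = c(roc_tan$auc, roc_tum$auc),
                     ci_low = c(roc_tan$ci_low, roc_tum$ci_low),
                     ci_high = c(roc_tan$ci_high, roc_tum$ci_high),
                     sensitivity = c(roc_tan$sensitivity,
                                     roc_tum$sensitivity),
                     specificity = c(roc_tan$specificity,
                                     roc_tum$specificity)),
          file.path(out, "auc_summary.csv"), row.names = FALSE)
write.csv(data.frame(z = dl$z, p = dl$p_value),
          file.path(out, "delong.csv"), row.names = FALSE)

# KM on the predicted risk groups
surv <- read.csv("results/cohort/survival.csv")
pfs <- surv[surv$endpoint == "PFS", ]
pid <- sub("_N$", "", names(cv_tan$prob))
srows <- pfs[match(pid, pfs$patient_id), ]
lr <- logrank_test(srows$time, srows$event, risk)
cat(sprintf("KM by predicted risk: log-rank p = %.4g (%d high / %d low)\n",
            lr$p_value, sum(risk == "high"), sum(risk == "low")))
write.csv(data.frame(chisq = lr$chisq, p = lr$p_value),
          file.path(out, "km_risk_logrank.csv"), row.names = FALSE)
cat("wrote", out, "\n")
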