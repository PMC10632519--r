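#!/usr/bin/env Rscript
# Survival association of module scores: KM high/low split of the top
# progression module, log-rank, multivariate Cox against clinical
# covariates, per-module c-index across endpoints, and the module-variable
# association map.

library(tanprog)

out <- "results/survival"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
scores <- read.csv("results/modules/module_scores.csv", row.names = 1)
scores <- as.matrix(scores)
meta <- read.csv("results/cohort/metadata.csv")
surv <- read.csv("results/cohort/survival.csv")
cp <- read.csv("results/modules/progression_comparison_tan.csv")

meta_n <- meta[meta$tissue == "normal", ]
sc_n <- scores[meta_n$sample_id, ]
top_mod <- cp$module[which.min(cp$p_value)]

pfs <- surv[surv$endpoint == "PFS", ]
srows <- pfs[match(meta_n$patient_id, pfs$patient_id), ]
si <- sc_n[, top_mod]
grp <- ifelse(si >= median(si), "high", "low")
km_high <- km_estimate(srows$time[grp == "high"],
                       srows$event[grp == "high"])
km_low <- km_estimate(srows$time[grp == "low"], srows$event[grp == "low"])
write.csv(rbind(data.frame(group = "high", time = km_high$time,
                           surv = km_high$surv, lo = km_high$ci_low,
                           hi = km_high$ci_high),
                data.frame(group = "low", time = km_low$time,
                           surv = km_low$surv, lo = km_low$ci_low,
                           hi = km_low$ci_high)),
          file.path(out, "km_curves.csv"), row.names = FALSE)
lr <- logrank_test(srows$time, srows$event, grp)
cat(sprintf("%s high/low (%d/%d): log-rank p = %.4g\n",
            top_mod, sum(grp == "high"), sum(grp == "low"), lr$p_value))

# multivariate Cox: module score + clinical covariates
cov <- data.frame(score = si,
                  age = meta_n$age,
                  male = as.integer(meta_n$sex == "M"),
                  grade = meta_n$grade)
cox <- multivariate_fit(srows, cov, "cox")
write.csv(cox, file.path(out, "multivariate_cox.csv"), row.names = FALSE)
cat(sprintf("Cox %s coefficient %.3f [%.3f, %.3f], Wald p = %.4g\n",
            top_mod, cox$coef[1], cox$ci_low[1], cox$ci_high[1],
            cox$p_value[1]))

# c-index of every module against each endpoint
cidx <- do.call(rbind, lapply(c("PFS", "RFS", "OS"), function(ep) {
  rows <- surv[surv$endpoint == ep, ]
  rr <- rows[match(meta_n$patient_id, rows$patient_id), ]
  data.frame(endpoint = ep, module = colnames(sc_n),
             c_index = apply(sc_n, 2, c_index, time = rr$time,
                             event = rr$event))
}))
write.csv(cidx, file.path(out, "c_index.csv"), row.names = FALSE)
best <- cidx[cidx$endpoint == "PFS", ]
cat(sprintf("highest PFS c-index: %s (%.3f)\n",
            best$module[which.max(best$c_index)], max(best$c_index)))

# association map
assoc <- associate_scores(sc_n, meta_n,
                          c(age = "continuous", sex = "binary",
                            grade = "ordinal", stage = "binary",
                            EGFR = "binary", KRAS = "binary",
                            TP53 = "binary", STK11 = "binary"))
write.csv(assoc, file.path(out, "association_map.csv"), row.names = FALSE)
cat(sprintf("association map: %d (module, variable) pairs, %d at p < 0.01\n",
            nrow(assoc), sum(assoc$p_value < 0.01, na.rm = TRUE)))
cat("wrote", out, "\n")
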