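#!/usr/bin/env Rscript
# Cell-type-resolved analysis on emulated deconvolution output: module
# scores per (patient, cell type), progression tests with Holm control,
# percent-positive cells, and fraction-score correlations.

library(tanprog)

out <- "results/celltypes"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
labels <- read.csv("results/preprocess/labels.csv")
scores <- read.csv("results/modules/module_scores.csv", row.names = 1)
cp <- read.csv("results/modules/progression_comparison_tan.csv")

# regenerate the cohort (same config/seed as 01) to attach cell-type data
cohort <- generate_cohort(cohort_config(seed = 1))
ctd <- generate_celltype_data(cohort, n_celltypes = 6, seed = 1,
                              n_cells_per = 4)
write.csv(data.frame(patient_id = rownames(ctd$fractions), ctd$fractions),
          file.path(out, "fractions.csv"), row.names = FALSE)

infl_genes <- names(which(cohort$truth$module_labels ==
                            cohort$truth$inflammatory_module_id))
cts <- celltype_module_score(ctd$expression, infl_genes)
write.csv(cts, file.path(out, "celltype_scores.csv"), row.names = FALSE)

cmp <- compare_celltype_progression(cts, labels)
write.csv(cmp, file.path(out, "celltype_progression.csv"),
          row.names = FALSE)
sig <- cmp$cell_type[cmp$significant_holm]
cat(sprintf("cell types with Holm p < 0.01: %s\n",
            if (length(sig)) paste(sig, collapse = ", ") else "none"))

cells <- cell_scores(ctd$cells, infl_genes)
pp <- percent_positive(cells)
write.csv(data.frame(cell_type = names(pp), percent_positive = pp),
          file.path(out, "percent_positive.csv"), row.names = FALSE)
cat("percent positive cells:",
    paste(sprintf("%s %.0f%%", names(pp), pp), collapse = ", "), "\n")

# fractions vs the bulk score of the top progression module
top_mod <- cp$module[which.min(cp$p_value)]
meta_order <- rownames(ctd$fractions)
bulk <- setNames(scores[paste0(meta_order, "_N"), top_mod], meta_order)
fc <- fraction_score_correlation(ctd$fractions, bulk)
write.csv(fc, file.path(out, "fraction_correlation.csv"),
          row.names = FALSE)
cat(sprintf("largest fraction-score correlation: %s (r = %.3f)\n",
            fc$cell_type[which.max(fc$estimate)], max(fc$estimate)))
cat("wrote", out, "\n")
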