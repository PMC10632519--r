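#!/usr/bin/env Rscript
# Simulate a matched tumor/TAN cohort with planted co-expression modules,
# an inflammatory module elevated in the TAN of progression-prone patients,
# and survival driven by that module's activity. Writes the cohort tables
# that the later analysis steps read back.

library(tanprog)

out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(seed = 1)  # 123 patients, 2000 genes, 20 modules
cohort <- generate_cohort(cfg)

write_counts(cohort$counts_tumor, file.path(out, "counts_tumor.tsv"))
write_counts(cohort$counts_normal, file.path(out, "counts_normal.tsv"))
write.csv(cohort$metadata, file.path(out, "metadata.csv"), row.names = FALSE)
write.csv(cohort$survival, file.path(out, "survival.csv"), row.names = FALSE)
write.table(
  data.frame(gene_id = names(cohort$truth$module_labels),
             module = cohort$truth$module_labels,
             loading = cohort$truth$loadings),
  file.path(out, "truth_modules.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
write.csv(
  data.frame(patient_id = names(cohort$truth$progression_prone),
             prone = cohort$truth$progression_prone,
             inflammatory_activity =
               cohort$truth$activity[, cfg$inflammatory_module_id, "normal"]),
  file.path(out, "truth_patients.csv"), row.names = FALSE)

ev <- cohort$survival[cohort$survival$endpoint == "PFS", "event"]
cat(sprintf("cohort: %d patients, %d genes; %d PFS events (%.0f%%)\n",
            cfg$n_patients, cfg$n_genes, sum(ev), 100 * mean(ev)))
cat("wrote", out, "\n")
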