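#!/usr/bin/env Rscript
# Unsupervised module discovery: variable-gene selection, gene-wise
# z-scoring, gene-space PCA, PAM clustering, module scores, and the
# tumor-vs-TAN and progression contrasts.

library(tanprog)

out <- "results/modules"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
expr <- readRDS("results/preprocess/expr.rds")
meta <- read.csv("results/cohort/metadata.csv")
labels <- read.csv("results/preprocess/labels.csv")

genes <- select_variable_genes(expr, 1000, "variance")
z <- scale_genes(expr[genes, ])
emb <- pca_genes(z, 10)
assignment <- pam_cluster(emb, k = 20)
scores <- module_score(z, assignment)

write.table(data.frame(gene_id = names(assignment$labels),
                       module = assignment$labels),
            file.path(out, "module_assignment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.csv(data.frame(sample_id = rownames(scores), scores),
          file.path(out, "module_scores.csv"), row.names = FALSE)

tissue <- meta$tissue[match(rownames(scores), meta$sample_id)]
ct <- compare_tissue(scores, tissue)
write.csv(ct, file.path(out, "tissue_comparison.csv"), row.names = FALSE)
cat(sprintf("%d/%d modules differ by tissue at BH 0.05\n",
            sum(ct$adjusted_p < 0.05), nrow(ct)))

cp <- compare_progression(scores, labels, meta, tissue = "normal")
write.csv(cp, file.path(out, "progression_comparison_tan.csv"),
          row.names = FALSE)
top <- cp[which.min(cp$p_value), ]
cat(sprintf("strongest TAN progression contrast: %s (p = %.2g, %s)\n",
            top$module, top$p_value, top$direction))

# how well does a reduced signature of that module track the full score?
mod_id <- as.integer(sub("M", "", top$module))
red <- do.call(rbind, lapply(c(5, 10, 20), function(n) {
  r <- reduced_signature(z, expr[genes, ], assignment, mod_id, n)
  data.frame(n = n, correlation = r$correlation)
}))
write.csv(red, file.path(out, "reduced_signature.csv"), row.names = FALSE)
cat("reduced-signature correlations:",
    paste(sprintf("n=%d r=%.3f", red$n, red$correlation), collapse = ", "),
    "\n")
cat("wrote", out, "\n")
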