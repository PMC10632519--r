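#!/usr/bin/env Rscript
# Normalize the simulated counts (median-of-ratios), apply the log
# transform, derive outcome labels, and filter a toy variant table down to
# the somatic calls that count toward tumor mutational burden.

library(tanprog)

cdir <- "results/cohort"
out <- "results/preprocess"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tumor <- read_counts(file.path(cdir, "counts_tumor.tsv"))
normal <- read_counts(file.path(cdir, "counts_normal.tsv"))
meta <- read.csv(file.path(cdir, "metadata.csv"))

counts <- cbind(tumor, normal)
sf <- size_factors(counts)
expr <- vst_transform(counts, sf)
write.csv(data.frame(sample_id = names(sf), size_factor = sf),
          file.path(out, "size_factors.csv"), row.names = FALSE)

labels <- derive_outcome_labels(meta)
write.csv(labels, file.path(out, "labels.csv"), row.names = FALSE)
cat(sprintf("labels: %d/%d/%d recurrence pos/neg/excluded\n",
            sum(labels$recurrence_5yr == "positive"),
            sum(labels$recurrence_5yr == "negative"),
            sum(labels$recurrence_5yr == "excluded")))

variants <- generate_variant_table(2000, seed = 1, n_samples = 123)
kept <- filter_variants(variants)
burden <- tmb(kept, sprintf("S%03d", 1:123))
write.csv(data.frame(sample_id = names(burden), tmb = burden),
          file.path(out, "tmb.csv"), row.names = FALSE)
cat(sprintf("variants: %d of %d survive the somatic filters; median TMB %d\n",
            nrow(kept), nrow(variants), median(burden)))

saveRDS(expr, file.path(out, "expr.rds"))  # scratch intermediate
cat("wrote", out, "\n")
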