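test_that("count matrices round-trip through TSV and MTX", {
  for (s in 1:3) {
    m <- random_counts(seed = s)
    tsv <- withr::local_tempfile(fileext = ".tsv")
    write_counts(m, tsv, "tsv")
    expect_identical(read_counts(tsv, "tsv"), m)
    mtx <- withr::local_tempfile(fileext = ".mtx")
    write_counts(m, mtx, "mtx")
    expect_identical(read_counts(mtx, "mtx"), m)
  }
})

test_that("malformed count files are rejected with the offending line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t4\t2", "g2\t-3\t1"), f)
  expect_error(read_counts(f, "tsv"), "line 3")
  writeLines(c("gene_id\ts1", "g1\t4", "g1\t2"), f)
  expect_error(read_counts(f, "tsv"), "duplicate gene ID")
  writeLines(c("gene_id\ts1", "g1\tfoo"), f)
  expect_error(read_counts(f, "tsv"), "line")
})

test_that("size factors follow the median-of-ratios definition", {
  m <- random_counts(seed = 2) + 1L  # no zeros
  # duplicated sample at double depth gets double the factor
  d <- cbind(m, double = 2L * m[, 1])
  f <- size_factors(d)
  expect_equal(unname(f["double"]), unname(2 * f[1]))
  # 3x2 worked example: factors proportional to (1, 2)
  toy <- matrix(c(2L, 8L, 2L, 4L, 16L, 4L), 3, 2,
                dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  ft <- size_factors(toy)
  expect_equal(unname(ft[2] / ft[1]), 2)
  # identical samples: all factors 1
  same <- cbind(m[, 1], m[, 1])
  dimnames(same) <- list(rownames(m), c("x", "y"))
  expect_equal(unname(size_factors(same)), c(1, 1))
})

test_that("size factors are permutation-invariant and scale-equivariant", {
  m <- random_counts(ng = 30, seed = 3) + 1L
  f <- size_factors(m)
  perm <- sample(nrow(m))
  expect_equal(size_factors(m[perm, ]), f)
  doubled <- m
  doubled[] <- 2L * m
  expect_equal(size_factors(doubled), f)  # global scaling cancels in ratios
})

test_that("the log transform is anchored and monotone", {
  m <- random_counts(seed = 4)
  m[1, 1] <- 0L
  e <- vst_transform(m, factors = rep(1, ncol(m)))
  expect_equal(e[1, 1], 0)
  m2 <- m; m2[2, 1] <- 7L
  expect_equal(vst_transform(m2, rep(1, ncol(m)))[2, 1], 3)
  ord <- order(m[, 2])
  expect_true(all(diff(e[ord, 2]) >= 0))
  expect_equal(attr(e, "transform_tag"), "log2_median_of_ratios")
  expect_error(vst_transform(m, rep(-1, ncol(m))), "positive")
})

test_that("variable-gene ranking follows the chosen statistic with ID tie-breaks", {
  e <- rbind(gene1 = rep(5, 6),
             gene2 = c(0, 1.5, 3, 4.5, 6, 7.5),
             gene3 = c(0, 0.5, 1, 1.5, 2, 2.5))
  colnames(e) <- paste0("s", 1:6)
  expect_identical(select_variable_genes(e, 3, "mad"),
                   c("gene2", "gene3", "gene1"))
  expect_identical(select_variable_genes(e, 99, "mad"),
                   c("gene2", "gene3", "gene1"))
  # outlier gene: huge variance but zero MAD beats a modest spread gene
  e2 <- rbind(spiky = c(rep(0, 9), 100),
              spread = 1:10 / 2)
  colnames(e2) <- paste0("s", 1:10)
  expect_identical(select_variable_genes(e2, 1, "variance")[1], "spiky")
  expect_identical(select_variable_genes(e2, 1, "mad")[1], "spread")
  # ties broken lexicographically
  tie <- rbind(b = 1:4, a = 1:4, c = 1:4)
  colnames(tie) <- paste0("s", 1:4)
  expect_identical(select_variable_genes(tie, 3, "variance"),
                   c("a", "b", "c"))
})

test_that("gene scaling gives exact z-scores and flags constant genes", {
  e <- rbind(g1 = c(1, 2, 3), g2 = c(4, 4, 4))
  colnames(e) <- paste0("s", 1:3)
  expect_warning(z <- scale_genes(e), "zero-variance")
  expect_equal(unname(z["g1", ]), c(-1, 0, 1))
  expect_equal(unname(z["g2", ]), c(0, 0, 0))
  expect_identical(attr(z, "zero_variance"), "g2")
  # idempotence on already-scaled rows
  z2 <- scale_genes(z[1, , drop = FALSE])
  expect_equal(z2[1, ], z[1, ], tolerance = 1e-12)
  # sample mean/sd contract on random data
  set.seed(5)
  r <- matrix(rnorm(80), 8, 10,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
  zr <- scale_genes(r)
  expect_true(all(abs(rowMeans(zr)) < 1e-10))
  expect_true(all(abs(apply(zr, 1, sd) - 1) < 1e-10))
})

test_that("outcome labels implement the 5-year boundary rules", {
  meta <- data.frame(
    patient_id = c("P1", "P2", "P3", "P4", "P5"),
    tissue = "normal",
    progression_type = c("second_primary", "systemic", "none",
                         "locoregional", "none"),
    followup_days = c(2000L, 100L, 1000L, 1826L, 1826L))
  lab <- derive_outcome_labels(meta)
  # second primary is progression but not recurrence; 2000 d > 5 yr follow-up
  expect_equal(lab$recurrence_5yr[lab$patient_id == "P1"], "negative")
  expect_equal(lab$progression_any[lab$patient_id == "P1"], "positive")
  # systemic at day 100
  expect_equal(lab$recurrence_5yr[lab$patient_id == "P2"], "positive")
  expect_equal(lab$rfs_event[lab$patient_id == "P2"], 1L)
  expect_equal(lab$rfs_time[lab$patient_id == "P2"], 100L)
  # no event, short follow-up
  expect_equal(lab$recurrence_5yr[lab$patient_id == "P3"], "excluded")
  expect_equal(lab$progression_any[lab$patient_id == "P3"], "excluded")
  # boundary day inclusive
  expect_equal(lab$recurrence_5yr[lab$patient_id == "P4"], "positive")
  expect_equal(lab$recurrence_5yr[lab$patient_id == "P5"], "negative")
  # missing follow-up excludes with warning
  meta$followup_days[3] <- NA
  expect_warning(lab2 <- derive_outcome_labels(meta), "missing follow-up")
  expect_false("P3" %in% lab2$patient_id)
})

test_that("variant filtering matches a row-by-row rule oracle", {
  base <- data.frame(VAF = 0.2, total_reads = 500L, alt_reads = 50L,
                     normal_VAF = 0, in_cosmic = TRUE, gnomad_freq = 0)
  rows <- base[rep(1, 7), ]
  rows$VAF[2] <- 0.005                  # fails VAF
  rows$total_reads[3] <- 99L            # fails depth
  rows$alt_reads[4] <- 4L               # fails alt reads
  rows$normal_VAF[5] <- 0.05            # fails 5x normal rule
  rows$in_cosmic[6] <- FALSE            # fails COSMIC
  rows$gnomad_freq[7] <- 0.002          # fails gnomAD
  kept <- filter_variants(rows)
  oracle <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    r$VAF > 0.01 && r$total_reads >= 100 && r$alt_reads >= 5 &&
      r$VAF > 5 * r$normal_VAF && r$in_cosmic && r$gnomad_freq < 0.001
  }, TRUE)
  expect_identical(rownames(kept), rownames(rows)[oracle])
  expect_equal(nrow(kept), 1)
  # boundary: VAF barely failing everything else passes
  expect_equal(nrow(filter_variants(transform(base, VAF = 0.005))), 0)
  # empty in, empty out; idempotent; permutation-commuting
  expect_equal(nrow(filter_variants(base[0, ])), 0)
  v <- generate_variant_table(100, seed = 9)
  expect_identical(filter_variants(filter_variants(v)), filter_variants(v))
  set.seed(1)
  perm <- sample(nrow(v))
  expect_setequal(rownames(filter_variants(v[perm, ])),
                  rownames(filter_variants(v)))
})

test_that("TMB counts retained variants per sample", {
  empty <- generate_variant_table(0)
  expect_equal(unname(tmb(empty, c("a", "b", "c"))), c(0L, 0L, 0L))
  v <- data.frame(sample_id = rep("s1", 5), VAF = 0.2, total_reads = 500L,
                  alt_reads = 50L, normal_VAF = 0, in_cosmic = TRUE,
                  gnomad_freq = 0)
  expect_equal(unname(tmb(v, "s1")), 5L)
  # group-by oracle on random tables
  set.seed(11)
  vt <- generate_variant_table(200, seed = 11)
  got <- tmb(vt, sort(unique(vt$sample_id)))
  oracle <- vapply(sort(unique(vt$sample_id)),
                   function(s) sum(vt$sample_id == s), 1L)
  expect_equal(got, oracle)
})
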