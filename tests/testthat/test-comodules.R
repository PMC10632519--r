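test_that("gene PCA matches a full eigendecomposition and is well-behaved", {
  # rank-1 matrix: PC1 carries all the variance
  set.seed(1)
  u <- rnorm(15); v <- rnorm(6)
  r1 <- outer(u, v)
  dimnames(r1) <- list(paste0("g", 1:15), paste0("s", 1:6))
  emb <- pca_genes(r1, 2)
  expect_gt(emb$explained_variance[1] / sum(emb$explained_variance), 1 - 1e-10)
  # eigen oracle on a 20 x 8 matrix
  set.seed(2)
  X <- matrix(rnorm(160), 20, 8,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:8)))
  emb <- pca_genes(X, 8)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)$values
  expect_equal(apply(emb$coordinates, 2, var), ev[1:8],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(emb$explained_variance) <= 1e-12))
  # sample-order permutation changes coordinates at most by per-PC sign
  set.seed(3)
  perm <- sample(8)
  emb_p <- pca_genes(X[, perm], 8)
  agree <- vapply(1:8, function(j)
    max(abs(abs(emb_p$coordinates[, j]) - abs(emb$coordinates[, j]))), 0)
  expect_true(all(agree < 1e-8))
  expect_error(pca_genes(X, 9), "n_pcs")
})

test_that("PAM is exact on trivial and well-separated instances", {
  set.seed(4)
  # k = n: every gene its own medoid, zero cost
  X <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("g", 1:6), NULL))
  emb <- list(coordinates = X, gene_ids = rownames(X))
  asg <- pam_cluster(emb, k = 6)
  expect_equal(asg$total_cost, 0)
  expect_setequal(asg$medoid_gene_ids, rownames(X))
  expect_error(pam_cluster(emb, k = 7), "exceeds")
  # two blobs separated by 50 sigma: exact blob recovery
  blob <- rbind(matrix(rnorm(40), 20, 2),
                matrix(rnorm(40, mean = 50), 20, 2))
  rownames(blob) <- paste0("g", 1:40)
  asg2 <- pam_cluster(list(coordinates = blob, gene_ids = rownames(blob)),
                      k = 2)
  expect_equal(length(unique(asg2$labels[1:20])), 1)
  expect_equal(length(unique(asg2$labels[21:40])), 1)
  expect_false(asg2$labels[1] == asg2$labels[40])
})

test_that("PAM attains the global optimum on exhaustively enumerable instances", {
  for (s in 1:8) {
    set.seed(s)
    X <- matrix(rnorm(16), 8, 2, dimnames = list(paste0("g", 1:8), NULL))
    asg <- pam_cluster(list(coordinates = X, gene_ids = rownames(X)), k = 2)
    expect_lte(asg$total_cost, asg$build_cost + 1e-12)
    D <- as.matrix(dist(X))
    best <- min(apply(utils::combn(8, 2), 2, function(med)
      sum(pmin(D[, med[1]], D[, med[2]]))))
    expect_equal(asg$total_cost, best, tolerance = 1e-10)
  }
})

test_that("module scores are per-module means of z-scores", {
  z <- matrix(c(1, -1, 0, 2, 0, -2, 3, 1, -1, -3, -1, 1), 3, 4,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  labels <- c(g1 = 1L, g2 = 1L, g3 = 2L)
  sc <- module_score(z, labels)
  expect_equal(sc[, "M1"], colMeans(z[c("g1", "g2"), ]))
  expect_equal(sc[, "M2"], z["g3", ])
  # z-score conservation: per-module mean over samples is ~0 on real z-scores
  co <- small_cohort(seed = 5)
  zz <- scale_genes(vst_transform(cbind(co$counts_tumor, co$counts_normal)))
  scc <- module_score(zz, co$truth$module_labels)
  expect_true(all(abs(colMeans(scc)) < 1e-10))
  # linearity: union of two disjoint modules = size-weighted mean
  merged <- co$truth$module_labels
  merged[merged == 2] <- 1L
  scm <- module_score(zz, merged)
  w <- c(40, 40)
  expect_equal(scm[, "M1"],
               (w[1] * scc[, "M1"] + w[2] * scc[, "M2"]) / sum(w))
  expect_error(module_score(zz, setNames(integer(3), c("x", "y", "z"))),
               "covers none")
})

test_that("tissue comparison uses the exact/approximate Wilcoxon engine", {
  sc <- matrix(c(4, 5, 6, 1, 2, 3), ncol = 1,
               dimnames = list(paste0("s", 1:6), "M1"))
  tissue <- c("tumor", "tumor", "tumor", "normal", "normal", "normal")
  res <- compare_tissue(sc, tissue)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$direction, "higher_in_tumor")
  # identical distributions: p = 1
  sc2 <- matrix(rep(c(1, 2, 3), 2), ncol = 1,
                dimnames = list(paste0("s", 1:6), "M1"))
  expect_equal(compare_tissue(sc2, tissue)$p_value, 1)
  expect_error(compare_tissue(sc[1:3, , drop = FALSE],
                              c("tumor", "tumor", "normal")),
               "at least 2")
  # engine agrees with full enumeration at n = 6 vs 6
  set.seed(6)
  x <- sample(100, 6); y <- sample(200, 6) + 100
  scr <- matrix(c(x, y), ncol = 1,
                dimnames = list(paste0("s", 1:12), "M1"))
  res2 <- compare_tissue(scr, rep(c("tumor", "normal"), each = 6))
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[1:6]) - 6 * 7 / 2
  combs <- utils::combn(12, 6)
  allr <- rank(c(x, y))
  w_all <- apply(combs, 2, function(idx) sum(allr[idx]) - 21)
  p_exact <- mean(abs(w_all - 18) >= abs(w_obs - 18))
  expect_equal(res2$p_value, p_exact, tolerance = 1e-12)
})

test_that("progression comparison pinpoints the planted module", {
  co <- small_cohort(seed = 7, inflammatory_effect = 2)
  z <- scale_genes(vst_transform(cbind(co$counts_tumor, co$counts_normal)))
  sc <- module_score(z, co$truth$module_labels)
  lab <- derive_outcome_labels(co$metadata)
  res <- compare_progression(sc, lab, co$metadata, "normal")
  infl <- paste0("M", co$truth$inflammatory_module_id)
  expect_equal(res$module[which.min(res$p_value)], infl)
  expect_equal(res$direction[res$module == infl], "up_in_progression")
  expect_true(all(res$adjusted_p >= res$p_value - 1e-15))
})

test_that("up/down percentages match a brute-force count", {
  labels <- setNames(rep(1:2, c(10, 5)), paste0("g", 1:15))
  flags <- setNames(rep("ns", 15), names(labels))
  flags[c("g1", "g2", "g3")] <- "up"
  flags[c("g4", "g5")] <- "down"
  ud <- updown_percentages(flags, labels)
  expect_equal(ud$percent_up[ud$module == "M1"], 30)
  expect_equal(ud$percent_down[ud$module == "M1"], 20)
  expect_equal(ud$percent_up[ud$module == "M2"], 0)
  # all ns
  ud0 <- updown_percentages(setNames(rep("ns", 15), names(labels)), labels)
  expect_true(all(ud0$percent_up == 0 & ud0$percent_down == 0))
  # random flags vs group-by oracle
  set.seed(8)
  rf <- setNames(sample(c("up", "down", "ns"), 15, TRUE), names(labels))
  udr <- updown_percentages(rf, labels)
  for (m in 1:2) {
    g <- names(labels)[labels == m]
    expect_equal(udr$percent_up[udr$module == paste0("M", m)],
                 100 * sum(rf[g] == "up") / length(g))
  }
  # flags for unknown genes are ignored with a warning
  expect_warning(updown_percentages(c(rf, zzz = "up"), labels), "missing")
})

test_that("reduced signatures clamp and correlate with the full score", {
  co <- small_cohort(seed = 9)
  expr <- vst_transform(cbind(co$counts_tumor, co$counts_normal))
  z <- scale_genes(expr)
  labels <- co$truth$module_labels
  m <- co$truth$inflammatory_module_id
  full_n <- sum(labels == m)
  rs_full <- reduced_signature(z, expr, labels, m, full_n)
  expect_equal(rs_full$correlation, 1)
  rs_over <- reduced_signature(z, expr, labels, m, full_n + 50)
  expect_setequal(rs_over$genes, rs_full$genes)
  rs10 <- reduced_signature(z, expr, labels, m, 10)
  expect_length(rs10$genes, 10)
  expect_gt(rs10$correlation, 0.8)  # coherent planted module
  # selected genes really are the most highly expressed module genes
  avg <- rowMeans(expr[names(labels)[labels == m], ])
  expect_setequal(rs10$genes, names(sort(avg, decreasing = TRUE))[1:10])
  expect_error(reduced_signature(z, expr, labels, m, 0), "n must be")
})

test_that("the adjusted Rand index matches an independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(25)
  for (i in 1:5) {
    a <- sample(1:4, 40, replace = TRUE)
    b <- sample(1:3, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})
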