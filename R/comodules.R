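#' PCA embedding of genes
#'
#' Principal components analysis with genes as observations (rows) and
#' samples as features, applied to a gene-wise z-scored expression matrix.
#' Features (samples) are centered; no rescaling.
#'
#' @param z Gene x sample z-scored matrix.
#' @param n_pcs Number of leading components to keep (default 10).
#' @return List of class `gene_embedding`: `coordinates` (genes x n_pcs),
#'   `explained_variance` (non-increasing), `gene_ids`.
#' @export
pca_genes <- function(z, n_pcs = 10) {
  if (n_pcs > min(dim(z)))
    stop("n_pcs exceeds matrix dimensions")
  pc <- prcomp(z, center = TRUE, scale. = FALSE)
  structure(list(
    coordinates = pc$x[, seq_len(n_pcs), drop = FALSE],
    explained_variance = pc$sdev[seq_len(n_pcs)]^2,
    gene_ids = rownames(z)), class = "gene_embedding")
}

#' Partitioning-around-medoids clustering of the gene embedding
#'
#' Classical PAM on Euclidean distances in the embedding space: greedy BUILD
#' seeding followed by SWAP local search, accepting any medoid/non-medoid
#' exchange that strictly lowers the total cost until a local optimum. All
#' ties are broken by the lowest gene index, making the result deterministic;
#' `seed` is accepted for interface symmetry and recorded.
#'
#' @param emb A [pca_genes()] embedding (or any list with a `coordinates`
#'   matrix and `gene_ids`).
#' @param k Number of modules (default 20).
#' @param seed Recorded seed (the algorithm itself is deterministic).
#' @return List of class `module_assignment`: `labels` (named integer vector
#'   gene -> module in 1..k), `medoid_gene_ids`, `total_cost`, `build_cost`.
#' @export
pam_cluster <- function(emb, k = 20, seed = 0L) {
  coords <- emb$coordinates
  n <- nrow(coords)
  if (k > n) stop("k exceeds the number of genes")
  if (k < 1) stop("k must be >= 1")
  res <- pam_cpp(coords, as.integer(k))
  labels <- setNames(as.integer(res$labels), emb$gene_ids)
  structure(list(
    labels = labels,
    medoid_gene_ids = emb$gene_ids[res$medoids],
    total_cost = res$total_cost,
    build_cost = res$build_cost,
    k = as.integer(k),
    seed = as.integer(seed)), class = "module_assignment")
}

#' Per-sample module scores
#'
#' The module score of sample s for module m is the mean over genes assigned
#' to m of the gene's z-score in s. Z-scores are expected to be computed
#' jointly over all samples (tumor and normal together), so scores share one
#' scale across tissues.
#'
#' @param z Gene x sample z-scored matrix covering the assigned genes.
#' @param assignment A [pam_cluster()] result or a named integer label
#'   vector (gene -> module; label 0 is ignored as background).
#' @return Samples x modules numeric matrix (columns `M1`..`Mk`).
#' @export
module_score <- function(z, assignment) {
  labels <- if (inherits(assignment, "module_assignment"))
    assignment$labels else assignment
  labels <- labels[names(labels) %in% rownames(z)]
  labels <- labels[labels > 0]
  if (!length(labels)) stop("assignment covers none of the matrix genes")
  mods <- sort(unique(labels))
  out <- vapply(mods, function(m) {
    genes <- names(labels)[labels == m]
    if (!length(genes)) stop("empty module ", m)
    colMeans(z[genes, , drop = FALSE])
  }, numeric(ncol(z)))
  out <- matrix(out, nrow = ncol(z),
                dimnames = list(colnames(z), paste0("M", mods)))
  out
}

# shared engine for per-module two-group Wilcoxon comparisons
compare_modules <- function(scores, group, level_a, level_b,
                            dir_labels = c("a", "b")) {
  ia <- which(group == level_a)
  ib <- which(group == level_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("each group needs at least 2 samples")
  res <- do.call(rbind, lapply(colnames(scores), function(m) {
    w <- wilcox_compare(scores[ia, m], scores[ib, m])
    data.frame(module = m, statistic = w$statistic, p_value = w$p_value,
               direction = if (w$median_diff >= 0) dir_labels[1]
                           else dir_labels[2],
               stringsAsFactors = FALSE)
  }))
  res$adjusted_p <- p.adjust(res$p_value, method = "BH")
  res
}

#' Compare module scores between tumor and normal tissue
#'
#' Two-sided Wilcoxon rank-sum test per module (exact for tie-free groups of
#' at most 10, otherwise normal approximation with continuity and tie
#' correction), direction by median difference, BH-adjusted across modules.
#'
#' @param scores Samples x modules score matrix.
#' @param tissue Character/factor per sample, values `"tumor"`/`"normal"`.
#' @return data.frame: module, statistic, p_value, direction
#'   (`higher_in_tumor` / `higher_in_normal`), adjusted_p.
#' @export
compare_tissue <- function(scores, tissue) {
  stopifnot(nrow(scores) == length(tissue))
  if (!all(c("tumor", "normal") %in% tissue))
    stop("both tissues must be present")
  compare_modules(scores, tissue, "tumor", "normal",
                  c("higher_in_tumor", "higher_in_normal"))
}

#' Compare module scores by progression status within a tissue
#'
#' Same test engine as [compare_tissue()], applied to progression vs
#' no-progression patients within the selected tissue.
#'
#' @param scores Samples x modules score matrix (rownames = sample IDs).
#' @param labels [derive_outcome_labels()] output (uses `progression_any`).
#' @param meta Sample metadata mapping sample_id to patient_id and tissue.
#' @param tissue Which tissue to test within (`"normal"` or `"tumor"`).
#' @return data.frame: module, statistic, p_value, direction
#'   (`up_in_progression` / `down_in_progression`), adjusted_p.
#' @export
compare_progression <- function(scores, labels, meta, tissue = "normal") {
  sm <- meta[meta$tissue == tissue, c("sample_id", "patient_id")]
  sm <- sm[sm$sample_id %in% rownames(scores), ]
  status <- labels$progression_any[match(sm$patient_id, labels$patient_id)]
  keep <- status %in% c("positive", "negative")
  sub <- scores[sm$sample_id[keep], , drop = FALSE]
  compare_modules(sub, status[keep], "positive", "negative",
                  c("up_in_progression", "down_in_progression"))
}

#' Rank-based differential-expression flags
#'
#' Per-gene two-sided Wilcoxon between two sample groups with BH adjustment;
#' genes with adjusted p below the cutoff are flagged `up` or `down` by the
#' sign of the median shift, others `ns`. A rank-based stand-in usable where
#' model-based differential expression results are not supplied.
#'
#' @param expr Gene x sample matrix (transformed scale).
#' @param group Logical/character per sample; `TRUE` (or `"case"`) vs rest.
#' @param fdr_cutoff Adjusted-p cutoff (default 0.05).
#' @return Named character vector per gene: `up`, `down` or `ns`.
#' @export
de_flags_rank <- function(expr, group, fdr_cutoff = 0.05) {
  g <- if (is.logical(group)) group else group == "case"
  if (sum(g) < 2 || sum(!g) < 2) stop("each group needs at least 2 samples")
  p <- apply(expr, 1, function(x)
    suppressWarnings(wilcox.test(x[g], x[!g], exact = FALSE,
                                 correct = TRUE)$p.value))
  shift <- apply(expr, 1, function(x) median(x[g]) - median(x[!g]))
  fdr <- p.adjust(p, "BH")
  flags <- ifelse(fdr < fdr_cutoff & shift > 0, "up",
                  ifelse(fdr < fdr_cutoff & shift < 0, "down", "ns"))
  setNames(flags, rownames(expr))
}

#' Percent up/down-regulated genes per module
#'
#' @param de_flags Named character vector per gene (`up`/`down`/`ns`).
#' @param assignment Module assignment ([pam_cluster()] result or named
#'   label vector).
#' @return data.frame per module: size, percent_up, percent_down.
#' @export
updown_percentages <- function(de_flags, assignment) {
  labels <- if (inherits(assignment, "module_assignment"))
    assignment$labels else assignment
  labels <- labels[labels > 0]
  extra <- setdiff(names(de_flags), names(labels))
  if (length(extra)) {
    warning(length(extra), " flagged gene(s) missing from assignment; ignored")
    de_flags <- de_flags[names(de_flags) %in% names(labels)]
  }
  mods <- sort(unique(labels))
  do.call(rbind, lapply(mods, function(m) {
    genes <- names(labels)[labels == m]
    fl <- de_flags[genes]
    fl[is.na(fl)] <- "ns"
    data.frame(module = paste0("M", m), size = length(genes),
               percent_up = 100 * sum(fl == "up") / length(genes),
               percent_down = 100 * sum(fl == "down") / length(genes))
  }))
}

#' Reduced module signature
#'
#' Takes the top-n genes of a module ranked by mean expression on the
#' (pre-z-scoring) transformed expression matrix and reports the Pearson
#' correlation of the reduced module score with the full module score across
#' samples. `n` beyond the module size clamps to the full module.
#'
#' @param z Gene x sample z-scored matrix (used for scoring).
#' @param expr Gene x sample transformed (pre-scaling) matrix (used for
#'   ranking by average expression).
#' @param assignment Module assignment.
#' @param module_id Module label (integer).
#' @param n Number of top genes (>= 1).
#' @return List: `genes` (selected IDs), `correlation`, `reduced_scores`,
#'   `full_scores`.
#' @export
reduced_signature <- function(z, expr, assignment, module_id, n) {
  if (n < 1) stop("n must be >= 1")
  labels <- if (inherits(assignment, "module_assignment"))
    assignment$labels else assignment
  genes <- names(labels)[labels == module_id]
  if (!length(genes)) stop("empty module ", module_id)
  avg <- rowMeans(expr[genes, , drop = FALSE])
  ranked <- genes[order(-avg, genes)]
  top <- ranked[seq_len(min(n, length(ranked)))]
  full <- colMeans(z[genes, , drop = FALSE])
  red <- colMeans(z[top, , drop = FALSE])
  r <- if (sd(red) == 0 || sd(full) == 0) NA_real_ else cor(red, full)
  if (length(top) == length(genes)) r <- 1
  list(genes = top, correlation = r, reduced_scores = red,
       full_scores = full)
}
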