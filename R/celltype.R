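#' Cell-type-resolved module score
#'
#' Z-scores every gene jointly across all (patient, cell type) expression
#' profiles, then averages the z-scores of the module genes per profile.
#' Joint scaling preserves between-cell-type differences. Log1p is applied
#' first since deconvolved profiles live on the count scale.
#'
#' @param expression Named list: cell type -> genes x patients matrix (a
#'   shared gene universe).
#' @param module_genes Gene IDs of the module; genes missing from the
#'   universe are dropped with a warning (at least one must remain).
#' @return data.frame: patient, cell_type, score.
#' @export
celltype_module_score <- function(expression, module_genes) {
  stopifnot(is.list(expression), length(expression) >= 1)
  genes <- rownames(expression[[1]])
  units <- do.call(cbind, lapply(names(expression), function(ct) {
    m <- expression[[ct]]
    if (!identical(rownames(m), genes))
      stop("cell types must share one gene universe")
    colnames(m) <- paste(colnames(m), ct, sep = "|")
    m
  }))
  present <- intersect(module_genes, genes)
  if (!length(present)) stop("no module genes present in the gene universe")
  if (length(present) < length(module_genes))
    warning(length(module_genes) - length(present),
            " module gene(s) missing from the universe; dropped")
  lz <- log1p(units)
  mu <- rowMeans(lz)
  s <- apply(lz, 1, sd)
  s[s == 0] <- 1
  z <- (lz - mu) / s
  sc <- colMeans(z[present, , drop = FALSE])
  parts <- strsplit(names(sc), "|", fixed = TRUE)
  data.frame(patient = vapply(parts, `[`, "", 1),
             cell_type = vapply(parts, `[`, "", 2),
             score = unname(sc), stringsAsFactors = FALSE)
}

#' Progression comparison of cell-type module scores
#'
#' Two-sided Mann-Whitney U per cell type between progression and
#' no-progression patients, Holm-adjusted across cell types. Both the raw
#' p < 0.01 rule and the Holm-adjusted p < 0.01 flag are reported. Cell
#' types with fewer than 2 patients in either group are skipped with a
#' warning.
#'
#' @param scores [celltype_module_score()] output.
#' @param labels [derive_outcome_labels()] output (uses `progression_any`).
#' @param alpha Significance cutoff (default 0.01).
#' @return data.frame per cell type: statistic, p_value, holm_p,
#'   significant_raw, significant_holm.
#' @export
compare_celltype_progression <- function(scores, labels, alpha = 0.01) {
  status <- labels$progression_any[match(scores$patient, labels$patient_id)]
  rows <- list()
  for (ct in unique(scores$cell_type)) {
    sel <- scores$cell_type == ct & status %in% c("positive", "negative")
    pos <- scores$score[sel & status == "positive"]
    neg <- scores$score[sel & status == "negative"]
    if (length(pos) < 2 || length(neg) < 2) {
      warning("cell type '", ct, "' skipped (group too small)")
      next
    }
    w <- wilcox_compare(pos, neg)
    rows[[length(rows) + 1L]] <- data.frame(
      cell_type = ct, statistic = w$statistic, p_value = w$p_value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no cell type had enough patients per group")
  out$holm_p <- adjust_holm(out$p_value)
  out$significant_raw <- out$p_value < alpha
  out$significant_holm <- out$holm_p < alpha
  out
}

#' Percentage of cells with a positive module score
#'
#' Per cell type: `100 * #(score > 0) / #cells` (zero does not count as
#' positive). Empty cell types are omitted.
#'
#' @param cell_scores data.frame with columns `cell_type` and `score` (one
#'   row per cell).
#' @return Named numeric vector, percentage per cell type.
#' @export
percent_positive <- function(cell_scores) {
  stopifnot(all(c("cell_type", "score") %in% names(cell_scores)))
  tapply(cell_scores$score, cell_scores$cell_type,
         function(s) 100 * mean(s > 0))
}

#' Per-cell module scores
#'
#' Mean z-score over module genes per cell, with genes z-scored jointly
#' across all cells of the log1p expression (a simplification of bin-matched
#' control-gene signature scoring).
#'
#' @param cells List with `expr` (genes x cells), `cell_type`, `patient`
#'   (as produced by [generate_celltype_data()]).
#' @param module_genes Gene IDs of the module.
#' @return data.frame: cell, cell_type, patient, score.
#' @export
cell_scores <- function(cells, module_genes) {
  present <- intersect(module_genes, rownames(cells$expr))
  if (!length(present)) stop("no module genes present")
  lz <- log1p(cells$expr)
  mu <- rowMeans(lz)
  s <- apply(lz, 1, sd)
  s[s == 0] <- 1
  z <- (lz - mu) / s
  data.frame(cell = colnames(cells$expr),
             cell_type = cells$cell_type,
             patient = cells$patient,
             score = unname(colMeans(z[present, , drop = FALSE])),
             stringsAsFactors = FALSE)
}

#' Correlation of cell-type fractions with the bulk module score
#'
#' Pearson correlation (and p) between each cell type's per-patient fraction
#' and the bulk module score across patients. Constant fractions give NA
#' with a warning.
#'
#' @param fractions Patients x cell types fraction matrix.
#' @param bulk_scores Named numeric vector of per-patient bulk module scores
#'   (names matching the fraction rownames).
#' @return data.frame per cell type: estimate, p_value.
#' @export
fraction_score_correlation <- function(fractions, bulk_scores) {
  pats <- intersect(rownames(fractions), names(bulk_scores))
  if (length(pats) < 3) stop("need at least 3 aligned patients")
  do.call(rbind, lapply(colnames(fractions), function(ct) {
    f <- fractions[pats, ct]
    if (sd(f) == 0) {
      warning("constant fraction for '", ct, "'; NA returned")
      return(data.frame(cell_type = ct, estimate = NA_real_,
                        p_value = NA_real_))
    }
    ctst <- cor.test(f, bulk_scores[pats], method = "pearson")
    data.frame(cell_type = ct, estimate = unname(ctst$estimate),
               p_value = ctst$p.value, stringsAsFactors = FALSE)
  }))
}
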