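#' Pipeline configuration
#'
#' Stage toggles and parameters for an end-to-end run on a synthetic cohort:
#' simulate -> preprocess -> modules -> enrichment -> classifier -> survival
#' -> cell types. Defaults follow the analysis conventions (k = 20 modules,
#' 10 PCs, MAD top-200 classifier genes, 10 outer / 10 inner folds).
#'
#' @param cohort Arguments passed to [cohort_config()].
#' @param stages Character vector of stages to run (dependency order is
#'   enforced; later stages needing a disabled stage are skipped).
#' @param n_variable Variable genes kept for module discovery.
#' @param n_pcs,k PCA depth and module count.
#' @param top_n,outer_folds,inner_folds,n_lambda,alphas Classifier settings.
#' @param n_celltypes Cell types for the deconvolution emulation.
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = list(),
                            stages = c("simulate", "preprocess", "modules",
                                       "enrichment", "classifier",
                                       "survival", "celltypes"),
                            n_variable = 1000, n_pcs = 10, k = 20,
                            top_n = 200, outer_folds = 10, inner_folds = 10,
                            n_lambda = 100, alphas = alpha_grid(),
                            n_celltypes = 6, seed = 0L) {
  cfg <- list(cohort = cohort, stages = stages, n_variable = n_variable,
              n_pcs = n_pcs, k = k, top_n = top_n,
              outer_folds = outer_folds, inner_folds = inner_folds,
              n_lambda = n_lambda, alphas = alphas,
              n_celltypes = n_celltypes, seed = as.integer(seed))
  stopifnot(n_variable >= k, n_pcs >= 1, top_n >= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in dependency order on a freshly simulated
#' cohort, writes each stage's tables under `out_dir`, and records a
#' manifest (parameters, seeds, file MD5 hashes) plus an exact copy of the
#' resolved configuration. Reruns with an identical configuration are
#' byte-identical for the deterministic stages.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  on <- function(stage) stage %in% config$stages
  res <- list()

  if (!on("simulate")) stop("missing upstream output: stage 'simulate'")
  ccfg <- do.call(cohort_config, c(config$cohort,
                                   if (is.null(config$cohort$seed))
                                     list(seed = config$seed)))
  cohort <- generate_cohort(ccfg)
  write_counts(cohort$counts_tumor, file.path(out_dir, "counts_tumor.tsv"))
  write_counts(cohort$counts_normal, file.path(out_dir, "counts_normal.tsv"))
  utils::write.csv(cohort$metadata, file.path(out_dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$survival, file.path(out_dir, "survival.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(inflammatory_module_id =
                          cohort$truth$inflammatory_module_id,
                        hazard_beta = cohort$truth$hazard_beta),
                   file.path(out_dir, "truth.yaml"))
  res$cohort <- cohort

  if (on("preprocess")) {
    counts <- cbind(cohort$counts_tumor, cohort$counts_normal)
    expr <- vst_transform(counts)
    labels <- derive_outcome_labels(cohort$metadata)
    utils::write.csv(labels, file.path(out_dir, "labels.csv"),
                     row.names = FALSE)
    res$expr <- expr
    res$labels <- labels
  }

  if (on("modules")) {
    if (!on("preprocess")) stop("missing upstream output: stage 'preprocess'")
    genes <- select_variable_genes(res$expr, config$n_variable, "variance")
    z <- scale_genes(res$expr[genes, , drop = FALSE])
    emb <- pca_genes(z, config$n_pcs)
    assignment <- pam_cluster(emb, config$k)
    scores <- module_score(z, assignment)
    write.table(data.frame(gene_id = names(assignment$labels),
                           module = assignment$labels),
                file.path(out_dir, "module_assignment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.csv(data.frame(sample_id = rownames(scores), scores),
                     file.path(out_dir, "module_scores.csv"),
                     row.names = FALSE)
    res$universe <- genes
    res$z <- z
    res$assignment <- assignment
    res$scores <- scores
  }

  if (on("enrichment")) {
    if (!on("modules")) stop("missing upstream output: stage 'modules'")
    truth_labels <- cohort$truth$module_labels
    planted <- split(names(truth_labels)[truth_labels > 0],
                     truth_labels[truth_labels > 0])
    names(planted) <- paste0("planted_", names(planted))
    sets <- lapply(planted, function(g) intersect(g, res$universe))
    sets <- sets[vapply(sets, length, 1L) > 0]
    mods <- split(names(res$assignment$labels), res$assignment$labels)
    names(mods) <- paste0("M", names(mods))
    enr <- fisher_enrichment(mods, sets, res$universe)
    utils::write.csv(enr, file.path(out_dir, "enrichment.csv"),
                     row.names = FALSE)
    res$enrichment <- enr
  }

  if (on("classifier")) {
    if (!on("preprocess")) stop("missing upstream output: stage 'preprocess'")
    meta_n <- cohort$metadata[cohort$metadata$tissue == "normal", ]
    lab <- res$labels
    rec <- setNames(ifelse(lab$recurrence_5yr == "positive", 1,
                           ifelse(lab$recurrence_5yr == "negative", 0, NA)),
                    meta_n$sample_id[match(lab$patient_id,
                                           meta_n$patient_id)])
    cvp <- nested_cv(res$expr[, meta_n$sample_id, drop = FALSE], rec,
                     outer_folds = config$outer_folds,
                     top_n = config$top_n, alphas = config$alphas,
                     inner_folds = config$inner_folds,
                     n_lambda = config$n_lambda, seed = config$seed)
    roc <- roc_auc(cvp$prob, cvp$y)
    utils::write.csv(data.frame(sample_id = names(cvp$prob),
                                prob = cvp$prob, y = cvp$y,
                                risk = stratify_risk(cvp)),
                     file.path(out_dir, "cv_predictions.csv"),
                     row.names = FALSE)
    yaml::write_yaml(list(auc = roc$auc, ci = c(roc$ci_low, roc$ci_high),
                          sensitivity = roc$sensitivity,
                          specificity = roc$specificity),
                     file.path(out_dir, "classifier_summary.yaml"))
    res$cv <- cvp
    res$roc <- roc
  }

  if (on("survival")) {
    if (!on("modules")) stop("missing upstream output: stage 'modules'")
    meta_n <- cohort$metadata[cohort$metadata$tissue == "normal", ]
    pfs <- cohort$survival[cohort$survival$endpoint == "PFS", ]
    infl <- paste0("M", cohort$truth$inflammatory_module_id)
    sc <- res$scores[meta_n$sample_id,
                     intersect(colnames(res$scores), infl), drop = FALSE]
    surv_rows <- pfs[match(meta_n$patient_id, pfs$patient_id), ]
    out <- list()
    if (ncol(sc) == 1) {
      grp <- ifelse(sc[, 1] >= median(sc[, 1]), "high", "low")
      lr <- logrank_test(surv_rows$time, surv_rows$event, grp)
      ci <- c_index(sc[, 1], surv_rows$time, surv_rows$event)
      out <- list(logrank_p = lr$p_value, c_index = ci)
      yaml::write_yaml(out, file.path(out_dir, "survival_summary.yaml"))
    }
    res$survival_summary <- out
  }

  if (on("celltypes")) {
    ctd <- generate_celltype_data(cohort, config$n_celltypes,
                                  seed = config$seed)
    infl_genes <- names(which(cohort$truth$module_labels ==
                                cohort$truth$inflammatory_module_id))
    cts <- celltype_module_score(ctd$expression, infl_genes)
    cmp <- compare_celltype_progression(cts, res$labels)
    utils::write.csv(cmp, file.path(out_dir, "celltype_progression.csv"),
                     row.names = FALSE)
    res$celltype <- list(data = ctd, scores = cts, comparison = cmp)
  }

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest|resolved_config", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("tanprog")),
    seed = config$seed,
    stages = config$stages,
    parameters = config[setdiff(names(config), "stages")],
    hashes = as.list(tools::md5sum(files)))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  yaml::write_yaml(unclass(config), file.path(out_dir,
                                              "resolved_config.yaml"))
  invisible(c(res, list(manifest = manifest)))
}
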