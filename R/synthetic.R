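#' Configuration for a synthetic matched tumor/normal cohort
#'
#' Defines the statistical structure of a simulated cohort: negative-binomial
#' counts with gene-level baselines and a mean-dependent dispersion trend,
#' block-correlated gene modules driven by per-patient latent activities, one
#' designated "inflammatory" module whose activity is elevated in the
#' tumor-adjacent normal (TAN) tissue of progression-prone patients, and
#' progression-free survival whose hazard increases with that activity.
#'
#' @param n_patients Number of patients (each contributes one tumor and one
#'   TAN sample).
#' @param n_genes Total number of genes.
#' @param n_modules Number of planted co-expression modules.
#' @param module_sizes Integer vector (length `n_modules`) of genes per
#'   module; must sum to at most `n_genes`. Remaining genes are unstructured
#'   background.
#' @param baseline_log_mean_range Range (natural-log scale) of per-gene
#'   baseline mean counts.
#' @param dispersion_coef,dispersion_floor NB dispersion
#'   `phi = dispersion_coef / mu + dispersion_floor`
#'   (variance `mu + mu^2 * phi`), mimicking the decreasing mean-dispersion
#'   trend of RNA-seq counts.
#' @param module_factor_sd SD of the per-patient, per-module, per-tissue
#'   latent activity.
#' @param inflammatory_module_id Which module carries the progression signal
#'   (default: the last module).
#' @param progression_fraction Fraction of patients designated
#'   progression-prone; also calibrates the baseline hazard so a patient with
#'   zero activity has this event probability by the follow-up horizon.
#' @param inflammatory_effect Latent activity added to the inflammatory
#'   module in TAN samples of progression-prone patients.
#' @param tissue_shift_sd SD of per-gene tumor-vs-normal log-mean shifts.
#' @param hazard_beta Log-hazard increase per unit of true TAN inflammatory
#'   activity.
#' @param censor_rate Fraction of patients receiving an independent
#'   Uniform(0, horizon) censoring time (all others are censored
#'   administratively at the horizon).
#' @param followup_horizon_days Administrative censoring horizon, in days.
#' @param loading_floor Lower bound applied to the half-normal gene loadings
#'   so every planted gene carries a detectable share of its module's signal.
#' @param seed Integer seed; identical configurations produce byte-identical
#'   cohorts.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 123L,
                          n_genes = 2000L,
                          n_modules = 20L,
                          module_sizes = rep(60L, 20L),
                          baseline_log_mean_range = c(log(5), log(500)),
                          dispersion_coef = 0.5,
                          dispersion_floor = 0.01,
                          module_factor_sd = 1,
                          inflammatory_module_id = n_modules,
                          progression_fraction = 45 / 123,
                          inflammatory_effect = 1,
                          tissue_shift_sd = 0.5,
                          hazard_beta = 1.5,
                          censor_rate = 0.2,
                          followup_horizon_days = 2920L,
                          loading_floor = 0.25,
                          seed = 0L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_genes = as.integer(n_genes),
              n_modules = as.integer(n_modules),
              module_sizes = as.integer(module_sizes),
              baseline_log_mean_range = baseline_log_mean_range,
              dispersion_coef = dispersion_coef,
              dispersion_floor = dispersion_floor,
              module_factor_sd = module_factor_sd,
              inflammatory_module_id = as.integer(inflammatory_module_id),
              progression_fraction = progression_fraction,
              inflammatory_effect = inflammatory_effect,
              tissue_shift_sd = tissue_shift_sd,
              hazard_beta = hazard_beta,
              censor_rate = censor_rate,
              followup_horizon_days = as.integer(followup_horizon_days),
              loading_floor = loading_floor,
              seed = as.integer(seed))
  if (cfg$n_patients < 1) stop("config error: n_patients must be >= 1")
  if (cfg$n_genes < 1) stop("config error: n_genes must be >= 1")
  if (length(cfg$module_sizes) != cfg$n_modules)
    stop("config error: module_sizes must have length n_modules")
  if (sum(cfg$module_sizes) > cfg$n_genes)
    stop("config error: module_sizes exceed n_genes")
  if (any(cfg$module_sizes < 1))
    stop("config error: module sizes must be positive")
  if (cfg$progression_fraction <= 0 || cfg$progression_fraction >= 1)
    stop("config error: progression_fraction must be in (0,1)")
  nonneg <- c(cfg$dispersion_coef, cfg$dispersion_floor, cfg$module_factor_sd,
              cfg$inflammatory_effect, cfg$tissue_shift_sd, cfg$censor_rate,
              cfg$loading_floor)
  if (any(nonneg < 0)) stop("config error: rates and SDs must be >= 0")
  if (cfg$censor_rate > 1) stop("config error: censor_rate must be <= 1")
  if (cfg$inflammatory_module_id < 1 ||
      cfg$inflammatory_module_id > cfg$n_modules)
    stop("config error: inflammatory_module_id out of range")
  if (cfg$followup_horizon_days < 1)
    stop("config error: followup_horizon_days must be positive")
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate a synthetic matched tumor/normal cohort
#'
#' Draws counts for one tumor and one TAN sample per patient. For gene g,
#' patient i and tissue t the NB mean is
#' `exp(baseline_g + shift_g * [t = tumor] + loading_g * activity[i, m(g), t])`
#' with latent activities drawn independently per tissue (module membership
#' and loadings are shared across tissues; mean shifts and activities are
#' tissue-specific). Progression-prone patients get `inflammatory_effect`
#' added to the TAN activity of the inflammatory module. Progression-free
#' survival is exponential with log-hazard `hazard_beta` per unit of that TAN
#' activity, censored independently and administratively at the horizon; the
#' observed progression type of each event is drawn multinomially
#' (second primary / locoregional / systemic).
#'
#' @param config A [cohort_config()].
#' @return List of class `synthetic_cohort` with elements `counts_tumor`,
#'   `counts_normal` (integer gene x sample matrices), `metadata` (one row
#'   per sample), `survival` (patient-level PFS/RFS/OS records), and `truth`
#'   (planted module labels, loadings, latent activities, prone indicator and
#'   hazard parameters).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  np <- config$n_patients
  ng <- config$n_genes
  k <- config$n_modules

  gene_ids <- sprintf("g%04d", seq_len(ng))
  patient_ids <- sprintf("P%03d", seq_len(np))

  module_labels <- integer(ng)  # 0 = background
  module_labels[seq_len(sum(config$module_sizes))] <-
    rep(seq_len(k), times = config$module_sizes)
  names(module_labels) <- gene_ids

  baseline <- runif(ng, config$baseline_log_mean_range[1],
                    config$baseline_log_mean_range[2])
  loading <- ifelse(module_labels > 0,
                    pmax(abs(rnorm(ng)), config$loading_floor), 0)
  tissue_shift <- rnorm(ng, 0, config$tissue_shift_sd)

  prone <- rbinom(np, 1, config$progression_fraction)
  # activity[patient, module, tissue]; tissue 1 = normal (TAN), 2 = tumor
  activity <- array(rnorm(np * k * 2, 0, config$module_factor_sd),
                    dim = c(np, k, 2),
                    dimnames = list(patient_ids, NULL, c("normal", "tumor")))
  activity[, config$inflammatory_module_id, "normal"] <-
    activity[, config$inflammatory_module_id, "normal"] +
    config$inflammatory_effect * prone

  draw_counts <- function(tissue) {
    act <- matrix(activity[, , tissue], nrow = np, ncol = k)
    # log-mean matrix genes x patients
    lm <- matrix(baseline, ng, np)
    if (tissue == "tumor") lm <- lm + tissue_shift
    planted <- module_labels > 0
    lm[planted, ] <- lm[planted, ] +
      loading[planted] * t(act[, module_labels[planted], drop = FALSE])
    # cap at a realistic library-depth ceiling; also keeps extreme latent
    # activities from overflowing integer count storage
    mu <- pmin(exp(lm), 5e6)
    phi <- config$dispersion_coef / mu + config$dispersion_floor
    cnt <- matrix(rnbinom(length(mu), mu = mu, size = 1 / phi), ng, np)
    dimnames(cnt) <- list(gene_ids,
                          paste0(patient_ids,
                                 if (tissue == "tumor") "_T" else "_N"))
    storage.mode(cnt) <- "integer"
    cnt
  }
  counts_normal <- draw_counts("normal")
  counts_tumor <- draw_counts("tumor")

  # survival: exponential PFS, baseline rate calibrated so an activity-0
  # patient has P(event by horizon) = progression_fraction
  horizon <- config$followup_horizon_days
  rate0 <- -log(1 - config$progression_fraction) / horizon
  infl_act <- activity[, config$inflammatory_module_id, "normal"]
  t_event <- rexp(np, rate0 * exp(config$hazard_beta * infl_act))
  c_time <- ifelse(runif(np) < config$censor_rate,
                   runif(np, 0, horizon), horizon)
  pfs_time <- pmax(1, round(pmin(t_event, c_time)))
  pfs_event <- as.integer(t_event <= c_time)

  prog_type <- rep("none", np)
  n_ev <- sum(pfs_event)
  if (n_ev > 0)
    prog_type[pfs_event == 1] <-
      sample(c("second_primary", "locoregional", "systemic"),
             n_ev, replace = TRUE, prob = c(0.3, 0.3, 0.4))

  # RFS: only locoregional/systemic count as events
  rfs_event <- as.integer(pfs_event == 1 &
                            prog_type %in% c("locoregional", "systemic"))
  rfs_time <- ifelse(rfs_event == 1, pfs_time,
                     pmax(1, round(c_time)))
  # OS: a fraction of progressors die after progression
  death_gap <- rexp(np, 1 / 400)
  dies <- pfs_event == 1 & runif(np) < 0.6
  os_time <- pmax(1, round(ifelse(dies, pmin(pfs_time + death_gap, horizon),
                                  pmax(1, round(c_time)))))
  os_event <- as.integer(dies & (pfs_time + death_gap) <= horizon)

  mut <- function(p) as.logical(rbinom(np, 1, p))
  pat_meta <- data.frame(
    patient_id = patient_ids,
    progression_type = prog_type,
    followup_days = as.integer(pfs_time),
    age = as.integer(pmax(35, pmin(92, round(rnorm(np, 69, 9))))),
    sex = sample(c("F", "M"), np, replace = TRUE, prob = c(0.6, 0.4)),
    grade = sample(1:3, np, replace = TRUE, prob = c(0.25, 0.45, 0.3)),
    stage = sample(c("IA", "IB"), np, replace = TRUE, prob = c(0.7, 0.3)),
    EGFR = mut(0.34), KRAS = mut(0.25), TP53 = mut(0.22), STK11 = mut(0.07),
    stringsAsFactors = FALSE)

  metadata <- rbind(
    data.frame(sample_id = colnames(counts_tumor), tissue = "tumor",
               pat_meta, stringsAsFactors = FALSE),
    data.frame(sample_id = colnames(counts_normal), tissue = "normal",
               pat_meta, stringsAsFactors = FALSE))
  metadata <- metadata[order(metadata$patient_id, metadata$tissue), ]
  rownames(metadata) <- NULL

  survival_tab <- data.frame(
    patient_id = rep(patient_ids, 3),
    endpoint = rep(c("PFS", "RFS", "OS"), each = np),
    time = c(pfs_time, rfs_time, os_time),
    event = c(pfs_event, rfs_event, os_event),
    stringsAsFactors = FALSE)

  structure(list(
    counts_tumor = counts_tumor,
    counts_normal = counts_normal,
    metadata = metadata,
    survival = survival_tab,
    truth = list(module_labels = module_labels,
                 baseline = setNames(baseline, gene_ids),
                 tissue_shift = setNames(tissue_shift, gene_ids),
                 loadings = setNames(loading, gene_ids),
                 activity = activity,
                 progression_prone = setNames(prone, patient_ids),
                 inflammatory_module_id = config$inflammatory_module_id,
                 hazard_beta = config$hazard_beta,
                 baseline_rate = rate0),
    config = config), class = "synthetic_cohort")
}

#' Generate cell-type-resolved expression emulating deconvolution output
#'
#' Decomposes the cohort's TAN counts into per-patient cell-type fractions
#' and cell-type-specific expression profiles such that the fraction-weighted
#' mixture reconstructs the bulk counts (up to multiplicative noise). One
#' designated cell type receives an increased affinity for the inflammatory
#' module's genes in progression-prone patients, so it carries the planted
#' elevation. A small per-cell expression matrix (Poisson resampling of the
#' profiles) is produced for per-cell scoring.
#'
#' @param cohort A [generate_cohort()] result.
#' @param n_celltypes Number of cell types (>= 2).
#' @param seed Integer seed.
#' @param n_cells_per Cells drawn per (patient, cell type) for the per-cell
#'   matrix.
#' @param profile_noise_sd SD of multiplicative log-normal noise on profiles.
#' @return List with `fractions` (patients x cell types, rows sum to 1),
#'   `expression` (named list: cell type -> genes x patients matrix),
#'   `cells` (list: `expr` genes x cells, `cell_type`, `patient`), and
#'   `designated` (the cell type carrying the planted elevation).
#' @export
generate_celltype_data <- function(cohort, n_celltypes = 6L, seed = 0L,
                                   n_cells_per = 5L, profile_noise_sd = 0.05) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (n_celltypes < 2) stop("config error: n_celltypes must be >= 2")
  set.seed(seed)
  pool <- c("monocyte", "epithelial", "macrophage", "fibroblast",
            "endothelial", "t_nk", "b_cell", "mast")
  ct_names <- if (n_celltypes <= length(pool)) pool[seq_len(n_celltypes)]
              else c(pool, sprintf("celltype_%d",
                                   seq_len(n_celltypes - length(pool))))
  designated <- ct_names[1]

  bulk <- cohort$counts_normal
  ng <- nrow(bulk)
  patient_ids <- cohort$truth$progression_prone
  np <- length(patient_ids)
  pid <- names(patient_ids)
  cfg <- cohort$config
  infl_genes <- names(which(cohort$truth$module_labels ==
                              cohort$truth$inflammatory_module_id))

  # Dirichlet fractions
  alpha <- runif(n_celltypes, 0.8, 3)
  g <- matrix(rgamma(np * n_celltypes, shape = rep(alpha, each = np)),
              np, n_celltypes)
  fractions <- g / rowSums(g)
  dimnames(fractions) <- list(pid, ct_names)

  # gene x cell-type affinities; designated type prefers inflammatory genes
  # more strongly in progression-prone patients
  pref <- matrix(rnorm(ng * n_celltypes, 0, 0.4), ng, n_celltypes,
                 dimnames = list(rownames(bulk), ct_names))
  base_aff <- exp(pref)

  expression <- lapply(ct_names, function(ct)
    matrix(0, ng, np, dimnames = list(rownames(bulk), pid)))
  names(expression) <- ct_names
  prone <- as.numeric(cohort$truth$progression_prone)

  for (i in seq_len(np)) {
    aff <- base_aff
    aff[infl_genes, designated] <- aff[infl_genes, designated] *
      exp(cfg$inflammatory_effect * prone[i])
    denom <- as.numeric(aff %*% fractions[i, ])
    denom[denom <= 0] <- 1e-12
    for (t in seq_len(n_celltypes)) {
      prof <- bulk[, i] * aff[, t] / denom
      expression[[t]][, i] <- prof *
        exp(rnorm(ng, 0, profile_noise_sd))
    }
  }

  # per-cell matrix: Poisson resampling of profiles at modest depth
  n_cells <- np * n_celltypes * n_cells_per
  cell_type <- character(n_cells)
  cell_patient <- character(n_cells)
  cell_expr <- matrix(0, ng, n_cells,
                      dimnames = list(rownames(bulk), NULL))
  idx <- 0L
  for (i in seq_len(np)) {
    for (t in seq_len(n_celltypes)) {
      prof <- expression[[t]][, i]
      lam <- prof / sum(prof) * 2000
      for (cc in seq_len(n_cells_per)) {
        idx <- idx + 1L
        cell_expr[, idx] <- rpois(ng, lam)
        cell_type[idx] <- ct_names[t]
        cell_patient[idx] <- pid[i]
      }
    }
  }
  colnames(cell_expr) <- sprintf("cell%05d", seq_len(n_cells))

  list(fractions = fractions, expression = expression,
       cells = list(expr = cell_expr, cell_type = cell_type,
                    patient = cell_patient),
       designated = designated)
}

#' Generate a toy somatic-variant table
#'
#' Draws variant-level fields from mixtures that span both sides of every
#' filtering threshold (VAF, depth, alt reads, matched-normal VAF, COSMIC
#' membership, gnomAD population frequency), so the filter is exercised in
#' all directions.
#'
#' @param n_variants Number of rows (>= 0).
#' @param seed Integer seed.
#' @param n_samples Number of sample IDs the variants are spread over.
#' @return data.frame with columns `sample_id`, `VAF`, `total_reads`,
#'   `alt_reads`, `normal_VAF`, `in_cosmic`, `gnomad_freq`.
#' @export
generate_variant_table <- function(n_variants, seed = 0L,
                                   n_samples = max(1L, ceiling(n_variants / 20))) {
  if (n_variants < 0) stop("n_variants must be >= 0")
  set.seed(seed)
  empty <- data.frame(sample_id = character(), VAF = numeric(),
                      total_reads = integer(), alt_reads = integer(),
                      normal_VAF = numeric(), in_cosmic = logical(),
                      gnomad_freq = numeric(), stringsAsFactors = FALSE)
  if (n_variants == 0) return(empty)
  low_vaf <- runif(n_variants) < 0.25
  vaf <- ifelse(low_vaf, runif(n_variants, 0, 0.03),
                rbeta(n_variants, 2, 6))
  depth <- ifelse(runif(n_variants) < 0.3,
                  rpois(n_variants, 60), rpois(n_variants, 400))
  alt <- rbinom(n_variants, depth, pmin(pmax(vaf, 1e-6), 1))
  nvaf <- ifelse(runif(n_variants) < 0.7, 0,
                 runif(n_variants, 0, 0.08))
  data.frame(
    sample_id = sample(sprintf("S%03d", seq_len(n_samples)),
                       n_variants, replace = TRUE),
    VAF = vaf,
    total_reads = as.integer(depth),
    alt_reads = as.integer(alt),
    normal_VAF = nvaf,
    in_cosmic = runif(n_variants) < 0.55,
    gnomad_freq = ifelse(runif(n_variants) < 0.6,
                         runif(n_variants, 0, 5e-4),
                         runif(n_variants, 0, 0.01)),
    stringsAsFactors = FALSE)
}
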