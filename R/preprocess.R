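#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: for each sample, the median over genes
#' (restricted to genes with a strictly positive geometric mean across
#' samples) of the ratio of the sample's count to the gene's geometric mean.
#'
#' @param counts Integer gene x sample matrix with dimnames.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  validate_counts(counts)
  log_geo <- rowMeans(log(counts))
  usable <- is.finite(log_geo)  # genes with no zero count in any sample
  if (!any(usable))
    stop("no gene with nonzero counts in every sample; cannot normalize")
  ratios <- counts[usable, , drop = FALSE] / exp(log_geo[usable])
  f <- apply(ratios, 2, median)
  if (any(f <= 0)) {
    bad <- colnames(counts)[f <= 0][1]
    stop("sample '", bad, "' has no usable nonzero genes")
  }
  f
}

#' Normalized log transformation of counts
#'
#' Variance-stabilizing-style transform: `log2(count / factor + 1)` per
#' sample. Monotone in the counts within each sample; a zero count maps to 0.
#'
#' @param counts Integer gene x sample matrix.
#' @param factors Positive per-sample size factors, aligned to columns
#'   (defaults to [size_factors()]).
#' @return Numeric matrix of the same shape with attribute `transform_tag`
#'   set to `"log2_median_of_ratios"`.
#' @export
vst_transform <- function(counts, factors = size_factors(counts)) {
  validate_counts(counts)
  if (length(factors) != ncol(counts))
    stop("factors must align with samples")
  if (any(factors <= 0)) stop("size factors must be positive")
  out <- log2(sweep(counts, 2, factors, "/") + 1)
  attr(out, "transform_tag") <- "log2_median_of_ratios"
  out
}

#' Rank genes by variability and take the top n
#'
#' @param expr Numeric gene x sample matrix (transformed scale).
#' @param n Number of genes to return (capped at the number of genes).
#' @param method `"variance"` (sample variance) or `"mad"` (median absolute
#'   deviation).
#' @return Character vector of gene IDs ordered by decreasing statistic;
#'   ties broken lexicographically by gene ID for determinism.
#' @export
select_variable_genes <- function(expr, n, method = c("variance", "mad")) {
  method <- match.arg(method)
  if (n < 1) stop("n must be >= 1")
  stat <- switch(method,
                 variance = apply(expr, 1, var),
                 mad = apply(expr, 1, mad))
  ord <- order(-stat, rownames(expr))
  rownames(expr)[ord][seq_len(min(n, nrow(expr)))]
}

#' Gene-wise z-scoring
#'
#' Centers and scales each gene to mean 0 and sample SD 1 (n - 1 denominator)
#' over the selected samples. Zero-variance genes are set to all zeros,
#' flagged in the `zero_variance` attribute and reported, not dropped, so
#' matrix shapes stay stable.
#'
#' @param expr Numeric gene x sample matrix.
#' @param sample_subset Optional character vector of sample IDs (or
#'   column indices) defining both the scaling statistics and the returned
#'   columns; default all samples.
#' @return Z-scored matrix over the selected samples, with attributes
#'   `transform_tag = "zscore"` and `zero_variance` (gene IDs zeroed).
#' @export
scale_genes <- function(expr, sample_subset = NULL) {
  x <- if (is.null(sample_subset)) expr else expr[, sample_subset, drop = FALSE]
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  flat <- s == 0 | !is.finite(s)
  s[flat] <- 1
  z <- (x - mu) / s
  z[flat, ] <- 0
  if (any(flat))
    warning(sum(flat), " zero-variance gene(s) set to 0 and flagged")
  attr(z, "transform_tag") <- "zscore"
  attr(z, "zero_variance") <- rownames(x)[flat]
  z
}

DAYS_5YR <- 1826L

#' Derive outcome labels and survival endpoints from sample metadata
#'
#' Recurrence (5-year) is positive iff a locoregional or systemic event
#' occurred within 1826 days; negative iff no such event and follow-up is at
#' least 1826 days; otherwise excluded. Progression (any type, including
#' second primaries) is labeled analogously. PFS counts any progression as
#' an event, RFS only locoregional/systemic; times are the event time, else
#' censoring at last follow-up. Boundary days are inclusive.
#'
#' @param meta Sample metadata with one row per patient per tissue
#'   (columns `patient_id`, `progression_type`, `followup_days`).
#' @return data.frame, one row per patient: `recurrence_5yr` and
#'   `progression_any` (factors positive/negative/excluded), `pfs_time`,
#'   `pfs_event`, `rfs_time`, `rfs_event`.
#' @export
derive_outcome_labels <- function(meta) {
  need <- c("patient_id", "progression_type", "followup_days")
  if (!all(need %in% names(meta)))
    stop("metadata must contain: ", paste(need, collapse = ", "))
  pat <- meta[!duplicated(meta$patient_id), need]
  missing_fu <- is.na(pat$followup_days)
  if (any(missing_fu)) {
    warning(sum(missing_fu), " patient(s) excluded for missing follow-up")
    pat <- pat[!missing_fu, ]
  }
  bad_type <- !pat$progression_type %in%
    c("none", "second_primary", "locoregional", "systemic")
  if (any(bad_type)) stop("unknown progression_type value(s)")

  is_rec <- pat$progression_type %in% c("locoregional", "systemic")
  is_prog <- pat$progression_type != "none"
  fu <- pat$followup_days

  # an event beyond 5 years is not a 5-year positive, but such follow-up
  # still qualifies the patient as a 5-year negative
  recurrence_5yr <- ifelse(is_rec & fu <= DAYS_5YR, "positive",
                           ifelse(fu >= DAYS_5YR, "negative", "excluded"))
  # progression positives have no time limit; negatives need >= 5y follow-up
  progression_any <- ifelse(is_prog, "positive",
                            ifelse(fu >= DAYS_5YR, "negative", "excluded"))

  data.frame(
    patient_id = pat$patient_id,
    recurrence_5yr = recurrence_5yr,
    progression_any = progression_any,
    pfs_time = fu,
    pfs_event = as.integer(is_prog),
    rfs_time = fu,
    rfs_event = as.integer(is_rec),
    stringsAsFactors = FALSE)
}

#' Filter somatic variant calls
#'
#' Keeps variants with VAF > 1%, at least 100 total reads, at least 5
#' alternate reads, VAF more than 5 times the matched-normal VAF, COSMIC
#' membership, and gnomAD population frequency below 0.1%. Row order is
#' preserved; the filter is a pointwise predicate.
#'
#' @param variants data.frame with columns `VAF`, `total_reads`, `alt_reads`,
#'   `normal_VAF`, `in_cosmic`, `gnomad_freq`.
#' @return The surviving rows, order preserved.
#' @export
filter_variants <- function(variants) {
  need <- c("VAF", "total_reads", "alt_reads", "normal_VAF", "in_cosmic",
            "gnomad_freq")
  if (!all(need %in% names(variants)))
    stop("variant table must contain: ", paste(need, collapse = ", "))
  if (nrow(variants) == 0) return(variants)
  keep <- variants$VAF > 0.01 &
    variants$total_reads >= 100 &
    variants$alt_reads >= 5 &
    variants$VAF > 5 * variants$normal_VAF &
    variants$in_cosmic &
    variants$gnomad_freq < 0.001
  variants[keep, , drop = FALSE]
}

#' Tumor mutational burden per sample
#'
#' Count of retained somatic variants per sample (raw count over the panel;
#' not normalized per megabase). Samples absent from the table get 0.
#'
#' @param filtered A variant table (typically [filter_variants()] output)
#'   with a sample key column.
#' @param sample_ids Character vector of all sample IDs to report.
#' @param per_sample_key Name of the sample key column.
#' @return Named integer vector of variant counts.
#' @export
tmb <- function(filtered, sample_ids, per_sample_key = "sample_id") {
  if (!per_sample_key %in% names(filtered))
    stop("missing sample key column '", per_sample_key, "'")
  counts <- table(factor(filtered[[per_sample_key]], levels = sample_ids))
  setNames(as.integer(counts), sample_ids)
}
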