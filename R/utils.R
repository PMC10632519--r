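#' Integer-rounded retention percentage
#'
#' Percentage of items retained after a quality-control step, rounded to the
#' nearest integer (e.g. 123 retained of 143 pairs gives 86).
#'
#' @param retained Number of items kept.
#' @param total Number of items before filtering.
#' @return Integer percentage.
#' @export
retention_percent <- function(retained, total) {
  stopifnot(is.numeric(retained), is.numeric(total), total > 0,
            retained >= 0, retained <= total)
  as.integer(round(100 * retained / total))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two label vectors over the same items.
#' Used to quantify recovery of planted co-expression modules by clustering.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return Adjusted Rand index in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# internal: validated counts matrix (genes x samples, named, non-negative ints)
validate_counts <- function(counts, what = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop(what, " must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop(what, " must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene IDs in ", what)
  if (any(counts < 0)) stop(what, " contains negative entries")
  if (any(counts != round(counts))) stop(what, " contains non-integer entries")
  invisible(counts)
}

# internal: two-group Wilcoxon rank-sum with the engine used throughout:
# exact enumeration when both groups have <= 10 tie-free observations,
# otherwise normal approximation with continuity and tie correction.
wilcox_compare <- function(x, y) {
  exact <- length(x) <= 10 && length(y) <= 10 &&
    !anyDuplicated(c(x, y))
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       median_diff = median(x) - median(y))
}
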