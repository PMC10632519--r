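#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields name, description,
#' then gene IDs. Duplicate genes within a set are deduplicated with a
#' warning; duplicate set names are an error.
#'
#' @param path GMT file path.
#' @return List of class `gene_set_collection`: `sets` (named list of gene ID
#'   vectors), `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3)
  if (length(short))
    stop("GMT parse error: fewer than 3 fields at line ", short[1])
  names_ <- vapply(fields, `[`, "", 1)
  if (anyDuplicated(names_))
    stop("duplicate set name '", names_[duplicated(names_)][1], "'")
  sets <- lapply(fields, function(f) {
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes in set '", f[1], "' deduplicated")
      genes <- unique(genes)
    }
    genes
  })
  names(sets) <- names_
  structure(list(sets = sets,
                 descriptions = setNames(vapply(fields, `[`, "", 2), names_)),
            class = "gene_set_collection")
}

#' Write a GMT gene-set collection
#'
#' @param collection A [read_gmt()]-style collection (or named list of gene
#'   vectors).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  sets <- if (inherits(collection, "gene_set_collection"))
    collection$sets else collection
  desc <- if (inherits(collection, "gene_set_collection"))
    collection$descriptions else setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement; the mapping back to
#' input positions is order-preserving.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @return Adjusted values, same order as input.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Holm family-wise-error adjustment
#'
#' Step-down Holm correction; order-preserving like [adjust_bh()].
#'
#' @param p Numeric p-values in \[0, 1\].
#' @return Adjusted values, same order as input.
#' @export
adjust_holm <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "holm")
}

#' One-tailed Fisher enrichment of modules against gene sets
#'
#' For every (module, set) pair, tests over-representation of the set among
#' the module's genes within the universe: p = P(X >= overlap) under the
#' hypergeometric null. Sets are intersected with the universe before
#' testing. The odds ratio comes from the 2x2 table (0.5 added to zero cells
#' for the ratio only). BH adjustment is applied jointly across the full
#' module x set grid.
#'
#' @param modules Named list: module -> gene IDs (each a subset of
#'   `universe`).
#' @param collection Gene-set collection ([read_gmt()] output or named list).
#' @param universe Character vector of background gene IDs (typically the
#'   genes submitted to module discovery).
#' @return data.frame per (module, set): overlap, module_size, set_size,
#'   universe_size, odds_ratio, p_value, fdr.
#' @export
fisher_enrichment <- function(modules, collection, universe) {
  sets <- if (inherits(collection, "gene_set_collection"))
    collection$sets else collection
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  if (!length(modules) || any(vapply(modules, length, 1L) == 0))
    stop("empty module")
  bad <- vapply(modules, function(g) !all(g %in% universe), TRUE)
  if (any(bad))
    stop("module genes outside the universe: ",
         names(modules)[bad][1])
  U <- length(universe)
  rows <- list()
  for (mn in names(modules)) {
    mg <- unique(modules[[mn]])
    for (sn in names(sets)) {
      sg <- intersect(sets[[sn]], universe)
      ov <- length(intersect(mg, sg))
      a <- ov
      b <- length(mg) - ov
      cc <- length(sg) - ov
      d <- U - length(mg) - length(sg) + ov
      p <- phyper(ov - 1, length(sg), U - length(sg), length(mg),
                  lower.tail = FALSE)
      tab <- c(a, b, cc, d)
      if (any(tab == 0)) tab <- tab + 0.5
      orat <- (tab[1] * tab[4]) / (tab[2] * tab[3])
      rows[[length(rows) + 1L]] <- data.frame(
        module = mn, set = sn, overlap = ov, module_size = length(mg),
        set_size = length(sg), universe_size = U, odds_ratio = orat,
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- adjust_bh(out$p_value)
  out
}
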