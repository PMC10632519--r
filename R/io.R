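#' Read a gene-by-sample count matrix
#'
#' Two plain-text layouts are supported. `tsv`: tab-separated with a header
#' row of sample IDs and the gene ID in the first column. `mtx`: MatrixMarket
#' coordinate format with sidecar ID files `<path>.rows` (gene IDs, one per
#' line) and `<path>.cols` (sample IDs).
#'
#' @param path Path to the TSV file or the `.mtx` file.
#' @param format One of `"tsv"`, `"mtx"`.
#' @return Integer matrix, genes in rows (rownames), samples in columns
#'   (colnames). Negative or non-integer entries are rejected.
#' @export
read_counts <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("malformed counts TSV (need gene column + samples)")
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids)) {
      dup <- ids[duplicated(ids)][1]
      stop("duplicate gene ID '", dup, "' at line ",
           which(ids == dup)[2] + 1L)
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(!apply(df[, -1, drop = FALSE], 1,
                          function(r) all(!is.na(suppressWarnings(as.numeric(r))))))[1]
      stop("non-numeric count at line ", bad + 1L)
    }
    rownames(m) <- ids
    bad <- which(apply(m, 1, function(r) any(r < 0 | r != round(r))))
    if (length(bad))
      stop("negative or non-integer count at line ", bad[1] + 1L)
    storage.mode(m) <- "integer"
    m
  } else {
    rows_f <- paste0(path, ".rows")
    cols_f <- paste0(path, ".cols")
    if (!file.exists(rows_f) || !file.exists(cols_f))
      stop("missing sidecar ID files ", rows_f, " / ", cols_f)
    sm <- Matrix::readMM(path)
    gene_ids <- readLines(rows_f)
    sample_ids <- readLines(cols_f)
    if (nrow(sm) != length(gene_ids) || ncol(sm) != length(sample_ids))
      stop("dimension mismatch between matrix and sidecar ID files")
    if (anyDuplicated(gene_ids)) stop("duplicate gene IDs in ", rows_f)
    m <- as.matrix(sm)
    dimnames(m) <- list(gene_ids, sample_ids)
    if (any(m < 0) || any(m != round(m)))
      stop("negative or non-integer entries in ", path)
    storage.mode(m) <- "integer"
    m
  }
}

#' Write a count matrix (TSV or MatrixMarket)
#'
#' Inverse of [read_counts()]; `mtx` writes `<path>`, `<path>.rows` and
#' `<path>.cols`.
#'
#' @param counts Integer matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param format One of `"tsv"`, `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  validate_counts(counts)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(path, ".rows"))
    writeLines(colnames(counts), paste0(path, ".cols"))
  }
  invisible(path)
}
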