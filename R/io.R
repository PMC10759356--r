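# Readers and writers for the standard on-disk formats: Matrix Market
# triplets with 10x-style companion files, dense TSV, and bulk CSV.

find_companion <- function(dir, base) {
  for (cand in c(base, paste0(base, ".gz"))) {
    p <- file.path(dir, cand)
    if (file.exists(p)) return(p)
  }
  NULL
}

read_id_column <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (!length(lines)) return(character())
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1)
}

#' Load a gene x cell count matrix
#'
#' Reads either a Matrix Market sparse matrix with 10x-style companions
#' (`matrix.mtx[.gz]` with `features.tsv[.gz]` and `barcodes.tsv[.gz]`, genes
#' as rows, 1-based coordinates) or a dense TSV with gene ids in the first
#' column and cell ids in the header. Gene and cell order is preserved
#' exactly as on disk; duplicated identifiers are an error, never
#' deduplicated silently.
#'
#' @param path For `"mtx"`: the directory holding the three files, or the
#'   `.mtx` file itself (companions are searched next to it). For `"tsv"`:
#'   the TSV file.
#' @param format `"mtx"` or `"tsv"`.
#' @return A [count_matrix()].
#' @export
load_counts <- function(path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    if (dir.exists(path)) {
      dir <- path
      mtx <- find_companion(dir, "matrix.mtx")
      if (is.null(mtx)) ps_stop("no matrix.mtx[.gz] found in ", dir)
    } else {
      if (!file.exists(path)) ps_stop("file not found: ", path)
      mtx <- path
      dir <- dirname(path)
    }
    feats <- find_companion(dir, "features.tsv") %||% find_companion(dir, "genes.tsv")
    bcs <- find_companion(dir, "barcodes.tsv")
    if (is.null(feats)) ps_stop("companion features.tsv[.gz] missing next to ", mtx)
    if (is.null(bcs)) ps_stop("companion barcodes.tsv[.gz] missing next to ", mtx)
    m <- Matrix::readMM(mtx)
    gene_ids <- read_id_column(feats)
    cell_ids <- read_id_column(bcs)
    count_matrix(as.matrix(m), gene_ids, cell_ids)
  } else {
    if (!file.exists(path)) ps_stop("file not found: ", path)
    tab <- read.delim(path, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, row.names = NULL)
    gene_ids <- as.character(tab[[1]])
    vals <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(vals)) ps_stop("non-numeric entries in ", path)
    count_matrix(vals, gene_ids, colnames(tab)[-1])
  }
}

#' Write a count matrix to disk
#'
#' `load_counts(write_counts(m, ...))` reproduces `m` exactly, including gene
#' and cell order and all-zero rows.
#'
#' @param m A [count_matrix()].
#' @param path For `"mtx"`: output directory (created if needed) receiving
#'   `matrix.mtx`, `features.tsv`, `barcodes.tsv`. For `"tsv"`: output file.
#' @param format `"mtx"` or `"tsv"`.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(m, path, format = c("mtx", "tsv")) {
  stopifnot(inherits(m, "CountMatrix"))
  format <- match.arg(format)
  if (format == "mtx") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    sp <- methods::as(Matrix::Matrix(m$counts, sparse = TRUE), "generalMatrix")
    Matrix::writeMM(sp, file.path(path, "matrix.mtx"))
    writeLines(m$gene_ids, file.path(path, "features.tsv"))
    writeLines(m$cell_ids, file.path(path, "barcodes.tsv"))
  } else {
    tab <- data.frame(gene = m$gene_ids, m$counts, check.names = FALSE,
                      stringsAsFactors = FALSE)
    colnames(tab) <- c("gene", m$cell_ids)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Load a bulk expression cohort from CSV
#'
#' Expects samples as rows (first column sample ids, header gene ids) or the
#' transpose with `transpose = TRUE`. Missing-value tokens are flagged as
#' `NA`, never coerced to zero; any other non-numeric token is an error that
#' names its row/column coordinates.
#'
#' @param path CSV file.
#' @param na_tokens Character tokens treated as missing.
#' @param transpose If `TRUE`, the file is genes x samples and is transposed
#'   on load.
#' @param labels Optional per-sample label vector attached to the cohort.
#' @return A [bulk_cohort()].
#' @export
load_bulk <- function(path, na_tokens = c("NA", "NaN", ""), transpose = FALSE,
                      labels = NULL) {
  if (!file.exists(path)) ps_stop("file not found: ", path)
  tab <- read.delim(path, sep = ",", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
  row_ids <- as.character(tab[[1]])
  cells <- as.matrix(tab[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(vals) & !(cells %in% na_tokens) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad)) {
    ps_stop("unparseable value '", cells[bad[1, 1], bad[1, 2]], "' at row ",
            row_ids[bad[1, 1]], ", column ", colnames(cells)[bad[1, 2]])
  }
  dimnames(vals) <- list(row_ids, colnames(cells))
  if (transpose) vals <- t(vals)
  bulk_cohort(vals, rownames(vals), colnames(vals), labels = labels)
}

#' Read a gene set from a text file (one gene id per line)
#'
#' @param path Text file; blank lines ignored.
#' @param name Set name (defaults to the file name).
#' @return A [gene_set()].
#' @export
load_gene_set <- function(path, name = NULL) {
  if (!file.exists(path)) ps_stop("file not found: ", path)
  genes <- readLines(path)
  genes <- genes[nzchar(trimws(genes))]
  gene_set(name %||% basename(path), trimws(genes))
}
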