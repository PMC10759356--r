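# Core containers.  All single-cell matrices are genes x cells; bulk cohorts
# are samples x genes (the direction in which the classifier transfers).

#' Construct a CountMatrix
#'
#' A `CountMatrix` holds raw UMI counts as a genes x cells integer matrix
#' together with unique gene and cell identifiers. It is the entry object of
#' the pipeline.
#'
#' @param counts Numeric matrix (genes x cells) of non-negative integers;
#'   dense or a [Matrix::sparseMatrix()].
#' @param gene_ids Character vector of unique gene identifiers (rows).
#' @param cell_ids Character vector of unique cell identifiers (columns).
#' @return An object of class `CountMatrix` with fields `counts`, `gene_ids`,
#'   `cell_ids`.
#' @export
count_matrix <- function(counts, gene_ids, cell_ids) {
  counts <- as(counts, "matrix")
  storage.mode(counts) <- "double"
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(counts) != length(gene_ids)) {
    ps_stop("counts has ", nrow(counts), " rows but ", length(gene_ids), " gene ids")
  }
  if (ncol(counts) != length(cell_ids)) {
    ps_stop("counts has ", ncol(counts), " columns but ", length(cell_ids), " cell ids")
  }
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) ps_stop("duplicate gene id(s): ", paste(head(dup_g, 5), collapse = ", "))
  dup_c <- unique(cell_ids[duplicated(cell_ids)])
  if (length(dup_c)) ps_stop("duplicate cell id(s): ", paste(head(dup_c, 5), collapse = ", "))
  if (length(counts) && (any(counts < 0) || any(counts != round(counts)))) {
    ps_stop("counts must be non-negative integers")
  }
  dimnames(counts) <- list(gene_ids, cell_ids)
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", length(x$gene_ids), "genes x", length(x$cell_ids), "cells\n")
  invisible(x)
}

#' Construct a NormalizedMatrix
#'
#' Holds TPM-like log-normalized expression: counts scaled to a fixed total
#' per cell, multiplied by `scale_factor` and natural-log transformed with a
#' pseudo-count of 1. Every downstream stage consumes this unit.
#'
#' @param values Numeric genes x cells matrix of non-negative reals.
#' @param gene_ids,cell_ids Unique identifiers matching `values` dimensions.
#' @param scale_factor Positive scale used at normalization (default 10000).
#' @param log_base Only `"natural"` is supported; recorded for provenance.
#' @return An object of class `NormalizedMatrix`.
#' @export
normalized_matrix <- function(values, gene_ids, cell_ids,
                              scale_factor = 10000, log_base = "natural") {
  values <- as(values, "matrix")
  storage.mode(values) <- "double"
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  stopifnot(nrow(values) == length(gene_ids), ncol(values) == length(cell_ids))
  if (anyDuplicated(gene_ids)) ps_stop("duplicate gene ids")
  if (anyDuplicated(cell_ids)) ps_stop("duplicate cell ids")
  if (length(values) && any(values < 0)) ps_stop("normalized values must be non-negative")
  log_base <- match.arg(log_base, "natural")
  stopifnot(scale_factor > 0)
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 scale_factor = scale_factor, log_base = log_base),
            class = "NormalizedMatrix")
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat("NormalizedMatrix:", length(x$gene_ids), "genes x", length(x$cell_ids),
      "cells (scale", x$scale_factor, ", natural log)\n")
  invisible(x)
}

#' Construct a per-cell annotation table
#'
#' Carries the sample of origin, normal/tumor group and cluster label of each
#' cell (cluster labels such as `"T00"` are inputs, not computed here).
#'
#' @param cell_id,sample_id,cluster Character vectors of equal length.
#' @param group Character vector with values `"normal"` or `"tumor"`.
#' @return A `data.frame` with class `CellAnnotation`.
#' @export
cell_annotation <- function(cell_id, sample_id, group, cluster) {
  cell_id <- as.character(cell_id)
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  cluster <- as.character(cluster)
  n <- length(cell_id)
  stopifnot(length(sample_id) == n, length(group) == n, length(cluster) == n)
  if (!all(group %in% c("normal", "tumor"))) {
    ps_stop("group must be 'normal' or 'tumor'")
  }
  if (any(!nzchar(cluster))) ps_stop("cluster labels must be non-empty")
  if (anyDuplicated(cell_id)) ps_stop("duplicate cell ids in annotation")
  structure(data.frame(cell_id = cell_id, sample_id = sample_id,
                       group = group, cluster = cluster,
                       stringsAsFactors = FALSE),
            class = c("CellAnnotation", "data.frame"))
}

#' Construct a GeneSet
#'
#' @param name Set name.
#' @param genes Non-empty character vector of unique gene ids.
#' @return An object of class `GeneSet`.
#' @export
gene_set <- function(name, genes) {
  genes <- as.character(genes)
  if (!length(genes)) ps_stop("gene set '", name, "' is empty")
  if (anyDuplicated(genes)) ps_stop("gene set '", name, "' has duplicate genes")
  structure(list(name = as.character(name), genes = genes), class = "GeneSet")
}

#' Construct a BulkCohort
#'
#' Bulk expression as samples x genes with explicit missing values (`NA`),
#' never silently zeroed. Optional per-sample labels (e.g. carcinoma /
#' invasive / non-invasive) travel with the matrix.
#'
#' @param values Numeric samples x genes matrix; `NA` marks missing entries.
#' @param sample_ids,gene_ids Unique identifiers.
#' @param labels Optional character vector of per-sample labels.
#' @return An object of class `BulkCohort`.
#' @export
bulk_cohort <- function(values, sample_ids, gene_ids, labels = NULL) {
  values <- as(values, "matrix")
  storage.mode(values) <- "double"
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  stopifnot(nrow(values) == length(sample_ids), ncol(values) == length(gene_ids))
  if (anyDuplicated(sample_ids)) ps_stop("duplicate sample ids")
  if (anyDuplicated(gene_ids)) ps_stop("duplicate gene ids")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    stopifnot(length(labels) == length(sample_ids))
  }
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 gene_ids = gene_ids, labels = labels),
            class = "BulkCohort")
}

#' @export
print.BulkCohort <- function(x, ...) {
  cat("BulkCohort:", length(x$sample_ids), "samples x", length(x$gene_ids),
      "genes;", sum(is.na(x$values)), "missing entries\n")
  invisible(x)
}
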