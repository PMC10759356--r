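# Cross-dataset cell assignment: restrict query and reference to a shared
# gene space, represent reference clusters by centroids, and assign query
# cells by maximal Pearson correlation (scmap-style).

#' Restrict two expression matrices to their shared gene space
#'
#' Without an ortholog map, genes are matched by case-normalized symbol
#' identity; with a map, reference symbols are first translated. Both
#' matrices are returned restricted to the shared genes in one canonical
#' order (query order).
#'
#' @param query,reference [normalized_matrix()] objects.
#' @param ortholog_map Optional named character vector mapping reference
#'   gene ids to query gene ids (one-to-one on its domain).
#' @return List with `query`, `reference` (both restricted) and
#'   `shared_genes`.
#' @export
harmonize_genes <- function(query, reference, ortholog_map = NULL) {
  stopifnot(inherits(query, "NormalizedMatrix"), inherits(reference, "NormalizedMatrix"))
  ref_ids <- reference$gene_ids
  if (!is.null(ortholog_map)) {
    if (anyDuplicated(ortholog_map) || anyDuplicated(names(ortholog_map))) {
      ps_stop("ortholog map must be one-to-one on its domain")
    }
    hit <- ref_ids %in% names(ortholog_map)
    ref_ids[hit] <- unname(ortholog_map[ref_ids[hit]])
    q_key <- query$gene_ids
    r_key <- ref_ids
  } else {
    q_key <- toupper(query$gene_ids)
    r_key <- toupper(ref_ids)
  }
  shared_q <- which(q_key %in% r_key)
  if (length(shared_q) < 50) {
    ps_stop("only ", length(shared_q), " shared genes (< 50); cannot harmonize")
  }
  q_idx <- shared_q
  r_idx <- match(q_key[shared_q], r_key)
  q <- normalized_matrix(query$values[q_idx, , drop = FALSE],
                         query$gene_ids[q_idx], query$cell_ids,
                         query$scale_factor)
  r <- normalized_matrix(reference$values[r_idx, , drop = FALSE],
                         query$gene_ids[q_idx], reference$cell_ids,
                         reference$scale_factor)
  list(query = q, reference = r, shared_genes = query$gene_ids[q_idx])
}

#' Per-cluster centroid profiles
#'
#' Represents each cluster by its centroid: the arithmetic mean of
#' log-normalized expression over its cells.
#'
#' @param nm A [normalized_matrix()].
#' @param clusters Per-cell cluster labels (named by cell id or in matrix
#'   order); labels must be non-empty and every cluster must have at least
#'   one cell.
#' @return List of `CentroidProfile` objects (fields `cluster`,
#'   `mean_expression`, `n_cells`), in sorted cluster-label order.
#' @export
compute_centroids <- function(nm, clusters) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  if (!is.null(names(clusters))) clusters <- clusters[nm$cell_ids]
  clusters <- as.character(clusters)
  stopifnot(length(clusters) == length(nm$cell_ids))
  if (any(is.na(clusters) | !nzchar(clusters))) ps_stop("empty cluster label")
  labs <- sort(unique(clusters))
  lapply(labs, function(cl) {
    idx <- which(clusters == cl)
    structure(list(cluster = cl,
                   mean_expression = rowMeans(nm$values[, idx, drop = FALSE]),
                   n_cells = length(idx)),
              class = "CentroidProfile")
  })
}

#' Map query cells onto reference centroids by Pearson correlation
#'
#' Computes the Pearson correlation between every query cell and every
#' centroid over the shared gene space and assigns each cell to the
#' arg-max centroid (ties broken by label order, logged). Zero-variance
#' cells or centroids get r = 0 for the affected pairs (logged). Cells with
#' `best_r < min_r` are labeled `"unassigned"`.
#'
#' @param query A [normalized_matrix()] whose gene order matches the
#'   centroids (use [harmonize_genes()] first).
#' @param centroids List of `CentroidProfile`s (from [compute_centroids()]).
#' @param min_r Minimal correlation for assignment (default -1: always
#'   assign).
#' @return Data frame with one row per cell: `cell_id`, `best_cluster`,
#'   `best_r`, plus one correlation column `r_<cluster>` per centroid.
#' @export
map_cells <- function(query, centroids, min_r = -1) {
  stopifnot(inherits(query, "NormalizedMatrix"), length(centroids) >= 1)
  cm <- centroid_matrix(centroids)
  if (!identical(rownames(cm), query$gene_ids)) {
    if (!all(query$gene_ids %in% rownames(cm))) {
      ps_stop("query genes do not match centroid genes; run harmonize_genes first")
    }
    cm <- cm[query$gene_ids, , drop = FALSE]
  }
  qv <- query$values
  sd_cell <- apply(qv, 2, sd)
  sd_cent <- apply(cm, 2, sd)
  r <- suppressWarnings(cor(qv, cm))
  bad <- sd_cell < 1e-12
  if (any(bad)) {
    ps_log(sum(bad), " zero-variance cell(s): correlations set to 0")
    r[bad, ] <- 0
  }
  if (any(sd_cent < 1e-12)) {
    ps_log(sum(sd_cent < 1e-12), " zero-variance centroid(s): correlations set to 0")
    r[, sd_cent < 1e-12] <- 0
  }
  r[is.na(r)] <- 0
  best_idx <- apply(r, 1, which.max)  # first maximum = label-order tie-break
  best_r <- r[cbind(seq_len(nrow(r)), best_idx)]
  best <- colnames(cm)[best_idx]
  best[best_r < min_r] <- "unassigned"
  out <- data.frame(cell_id = query$cell_ids, best_cluster = best,
                    best_r = best_r, stringsAsFactors = FALSE)
  rcols <- as.data.frame(r)
  colnames(rcols) <- paste0("r_", colnames(cm))
  cbind(out, rcols, stringsAsFactors = FALSE)
}
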