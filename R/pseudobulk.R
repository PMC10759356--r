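# Pseudo-bulk profiles, principal-component cosine similarity between
# samples, and the transcription-factor dendrogram between clusters.

#' Build pseudo-bulk profiles
#'
#' The pseudo-bulk of each sample is the gene-wise sum of log-normalized
#' expression over all its cells (no re-normalization).
#'
#' @param nm A [normalized_matrix()].
#' @param sample_of_cell Per-cell sample labels (named by cell id or in
#'   matrix order); every cell must be labeled.
#' @return List of `PseudobulkProfile` objects (fields `sample_id`,
#'   `summed_expression`, `n_cells`), in sorted sample order.
#' @export
build_pseudobulk <- function(nm, sample_of_cell) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  if (!is.null(names(sample_of_cell))) sample_of_cell <- sample_of_cell[nm$cell_ids]
  sample_of_cell <- as.character(sample_of_cell)
  stopifnot(length(sample_of_cell) == length(nm$cell_ids))
  if (any(is.na(sample_of_cell))) ps_stop("every cell needs a sample label")
  labs <- sort(unique(sample_of_cell))
  lapply(labs, function(s) {
    idx <- which(sample_of_cell == s)
    structure(list(sample_id = s,
                   summed_expression = rowSums(nm$values[, idx, drop = FALSE]),
                   n_cells = length(idx)),
              class = "PseudobulkProfile")
  })
}

profile_matrix <- function(profiles) {
  genes <- names(profiles[[1]]$summed_expression)
  m <- t(vapply(profiles, function(p) p$summed_expression[genes],
                numeric(length(genes))))
  rownames(m) <- vapply(profiles, function(p) p$sample_id, character(1))
  colnames(m) <- genes
  m
}

#' Principal-component embedding of observation profiles
#'
#' Centers (and by default unit-variance scales) each gene across
#' observations, drops constant genes with a log line, and projects onto
#' the top principal components via singular value decomposition. Axis
#' signs are fixed deterministically: the largest-magnitude loading of each
#' component is made positive.
#'
#' @param profiles Observations x genes numeric matrix, or a list of
#'   `PseudobulkProfile`s.
#' @param n_pcs Number of components (default 20, must not exceed
#'   `min(observations - 1, genes)`).
#' @param scale Scale genes to unit variance (default `TRUE`).
#' @return Observations x `n_pcs` coordinate matrix (rows named as input)
#'   with the component variances as attribute `"sdev"`.
#' @export
pc_embed <- function(profiles, n_pcs = 20, scale = TRUE) {
  x <- if (is.list(profiles) && !is.matrix(profiles)) profile_matrix(profiles) else profiles
  stopifnot(is.matrix(x))
  if (nrow(x) < 2) ps_stop("need at least two observations")
  sds <- apply(x, 2, sd)
  if (any(sds < 1e-12)) {
    ps_log(sum(sds < 1e-12), " constant gene(s) dropped before PCA")
    x <- x[, sds >= 1e-12, drop = FALSE]
    sds <- sds[sds >= 1e-12]
  }
  if (n_pcs > min(nrow(x) - 1, ncol(x))) {
    ps_stop("n_pcs exceeds min(observations - 1, genes) = ",
            min(nrow(x) - 1, ncol(x)))
  }
  xc <- scale(x, center = TRUE, scale = scale)
  sv <- svd(xc, nu = n_pcs, nv = n_pcs)
  # deterministic sign: largest-|loading| entry of each axis positive
  for (j in seq_len(n_pcs)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  coords <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  rownames(coords) <- rownames(x)
  colnames(coords) <- paste0("PC", seq_len(n_pcs))
  attr(coords, "sdev") <- sv$d / sqrt(max(1, nrow(x) - 1))
  coords
}

#' Pairwise cosine similarity matrix
#'
#' `S(i, j) = <u_i, u_j> / (||u_i|| ||u_j||)`; symmetric with unit
#' diagonal. All-zero rows give similarity 0 for their pairs (logged) and
#' keep a unit diagonal.
#'
#' @param coords Observations x dimensions matrix (e.g. from [pc_embed()]).
#' @return An object of class `SimilarityMatrix`: list with `ids` and
#'   square `values` in `[-1, 1]`.
#' @export
cosine_similarity_matrix <- function(coords) {
  stopifnot(is.matrix(coords))
  nrm <- sqrt(rowSums(coords^2))
  zero <- nrm < 1e-300
  if (any(zero)) ps_log(sum(zero), " all-zero row(s): their similarities set to 0")
  nrm[zero] <- 1
  u <- coords / nrm
  s <- u %*% t(u)
  s[zero, ] <- 0
  s[, zero] <- 0
  diag(s) <- 1
  s <- pmin(pmax(s, -1), 1)
  ids <- rownames(coords) %||% as.character(seq_len(nrow(coords)))
  dimnames(s) <- list(ids, ids)
  structure(list(ids = ids, values = s), class = "SimilarityMatrix")
}

#' Cluster dendrogram from transcription-factor expression
#'
#' Restricts a scaled expression matrix to a transcription-factor gene
#' list, embeds the cells in principal-component space, averages each
#' cluster's coordinates, computes pairwise Euclidean distances between the
#' cluster means, and builds an agglomerative dendrogram.
#'
#' @param sm A `ScaledMatrix` (from [regress_scale()]).
#' @param clusters Per-cell cluster labels (named by cell id or in matrix
#'   order); at least two clusters.
#' @param tf_genes Character vector of transcription-factor gene ids (the
#'   intersection with the matrix must be non-empty).
#' @param n_pcs Number of principal components (default 20, capped at the
#'   available rank).
#' @param linkage `"complete"` (default), `"average"` or `"ward"`.
#' @return List of class `DendrogramResult` with `hclust` (the merge
#'   history), `distances` (between cluster means), `labels` and `newick`
#'   (Newick text of the tree).
#' @export
cluster_dendrogram <- function(sm, clusters, tf_genes, n_pcs = 20,
                               linkage = c("complete", "average", "ward")) {
  stopifnot(inherits(sm, "ScaledMatrix"))
  linkage <- match.arg(linkage)
  if (!is.null(names(clusters))) clusters <- clusters[sm$cell_ids]
  clusters <- as.character(clusters)
  stopifnot(length(clusters) == length(sm$cell_ids))
  if (length(unique(clusters)) < 2) ps_stop("need at least two clusters")
  genes <- intersect(tf_genes, sm$gene_ids)
  if (!length(genes)) ps_stop("no transcription-factor genes present in the matrix")
  x <- t(sm$values[genes, , drop = FALSE])  # cells x TF genes, already scaled
  n_pcs <- min(n_pcs, nrow(x) - 1, ncol(x))
  coords <- pc_embed(x, n_pcs = n_pcs, scale = FALSE)
  labs <- sort(unique(clusters))
  means <- t(vapply(labs, function(cl) {
    colMeans(coords[clusters == cl, , drop = FALSE])
  }, numeric(ncol(coords))))
  d <- dist(means)
  hc <- hclust(d, method = if (linkage == "ward") "ward.D2" else linkage)
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(hclust = hc, distances = d, labels = labs, linkage = linkage,
                 newick = newick),
            class = "DendrogramResult")
}
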