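# Quality control, TPM-like log normalization, highly-variable-gene
# selection and covariate-regressed scaling.

#' Quality-control thresholds
#'
#' The four per-cell filters (UMI count range, detected-gene range, maximal
#' mitochondrial fraction, maximal dissociation-gene fraction) plus the
#' minimal number of cells a gene must be detected in. Numeric cutoffs are
#' configuration, not constants: defaults cover typical 10x data, and the
#' reference-atlas convention (at least 200 genes, at most 50% mitochondrial
#' counts) is available as `qc_thresholds(genes_min = 200, mito_max = 0.5)`.
#'
#' @param umi_min,umi_max Allowed range of total UMIs per cell.
#' @param genes_min,genes_max Allowed range of detected genes per cell.
#' @param mito_max Maximal fraction of counts from mitochondrial genes.
#' @param dissoc_max Maximal fraction from dissociation-associated genes.
#' @param min_cells_per_gene Genes detected in fewer cells are removed.
#' @return An object of class `QCThresholds`.
#' @export
qc_thresholds <- function(umi_min = 500, umi_max = 60000,
                          genes_min = 200, genes_max = 8000,
                          mito_max = 0.2, dissoc_max = 0.05,
                          min_cells_per_gene = 3) {
  stopifnot(umi_min <= umi_max, genes_min <= genes_max,
            mito_max >= 0, mito_max <= 1, dissoc_max >= 0, dissoc_max <= 1,
            min_cells_per_gene >= 0)
  structure(list(umi_min = umi_min, umi_max = umi_max,
                 genes_min = genes_min, genes_max = genes_max,
                 mito_max = mito_max, dissoc_max = dissoc_max,
                 min_cells_per_gene = min_cells_per_gene),
            class = "QCThresholds")
}

#' Apply quality-control filters to a count matrix
#'
#' Cells are filtered first (UMI range, detected-gene range, mitochondrial
#' fraction, dissociation fraction), then genes detected in fewer than
#' `min_cells_per_gene` of the remaining cells are removed. The report lists
#' per-filter removal counts.
#'
#' @param m A [count_matrix()].
#' @param gene_flags List with optional character vectors `mito` and
#'   `dissoc` naming flagged genes (must be subsets of `m$gene_ids`).
#' @param thresholds A [qc_thresholds()].
#' @return A list with `counts` (filtered [count_matrix()]) and `report`
#'   (per-filter removal counts and retained dimensions).
#' @export
apply_qc <- function(m, gene_flags = list(), thresholds = qc_thresholds()) {
  stopifnot(inherits(m, "CountMatrix"), inherits(thresholds, "QCThresholds"))
  mito <- gene_flags$mito %||% character()
  dissoc <- gene_flags$dissoc %||% character()
  bad <- setdiff(c(mito, dissoc), m$gene_ids)
  if (length(bad)) ps_stop("flagged gene(s) absent from matrix: ",
                           paste(head(bad, 5), collapse = ", "))
  x <- m$counts
  total <- colSums(x)
  ngene <- colSums(x > 0)
  mito_frac <- if (length(mito)) colSums(x[mito, , drop = FALSE]) / pmax(total, 1) else rep(0, ncol(x))
  dissoc_frac <- if (length(dissoc)) colSums(x[dissoc, , drop = FALSE]) / pmax(total, 1) else rep(0, ncol(x))

  fail_umi <- total < thresholds$umi_min | total > thresholds$umi_max
  fail_genes <- ngene < thresholds$genes_min | ngene > thresholds$genes_max
  fail_mito <- mito_frac > thresholds$mito_max
  fail_dissoc <- dissoc_frac > thresholds$dissoc_max
  keep_cells <- !(fail_umi | fail_genes | fail_mito | fail_dissoc)

  report <- list(
    cells_in = ncol(x),
    removed_umi = sum(fail_umi),
    removed_genes_detected = sum(fail_genes),
    removed_mito = sum(fail_mito),
    removed_dissociation = sum(fail_dissoc),
    cells_removed = sum(!keep_cells)
  )
  if (!any(keep_cells)) {
    ps_stop("all cells removed by QC (umi: ", report$removed_umi,
            ", genes: ", report$removed_genes_detected,
            ", mito: ", report$removed_mito,
            ", dissociation: ", report$removed_dissociation, ")")
  }
  x <- x[, keep_cells, drop = FALSE]
  detected_in <- rowSums(x > 0)
  keep_genes <- detected_in >= thresholds$min_cells_per_gene
  report$genes_in <- nrow(x)
  report$genes_removed <- sum(!keep_genes)
  x <- x[keep_genes, , drop = FALSE]
  report$cells_out <- ncol(x)
  report$genes_out <- nrow(x)
  ps_log("QC: removed ", report$cells_removed, "/", report$cells_in, " cells and ",
         report$genes_removed, "/", report$genes_in, " genes")
  list(counts = count_matrix(x, rownames(x), colnames(x)), report = report)
}

#' TPM-like log normalization
#'
#' Each gene's count is divided by the cell's total UMI count, multiplied by
#' `scale_factor` (default 10,000) and natural-log transformed after adding
#' a pseudo-count of 1:
#' `value(g, c) = log(count(g, c) / total(c) * scale_factor + 1)`.
#'
#' @param m A [count_matrix()]; every cell must have total count > 0.
#' @param scale_factor Positive scale (default 10000).
#' @return A [normalized_matrix()].
#' @export
lognormalize <- function(m, scale_factor = 10000) {
  stopifnot(inherits(m, "CountMatrix"), scale_factor > 0)
  total <- colSums(m$counts)
  zero <- which(total == 0)
  if (length(zero)) {
    ps_stop("cell(s) with zero total count: ",
            paste(head(m$cell_ids[zero], 5), collapse = ", "))
  }
  vals <- log1p(sweep(m$counts, 2, total, "/") * scale_factor)
  normalized_matrix(vals, m$gene_ids, m$cell_ids, scale_factor = scale_factor)
}

#' Select highly variable genes (variance-stabilizing style)
#'
#' Ranks genes by variance standardized against a smooth mean-variance
#' trend fitted on raw counts: a local polynomial regression of
#' log10(variance) on log10(mean) (span 0.3) predicts each gene's expected
#' standard deviation; per-cell counts are standardized by it, clipped at
#' `sqrt(n_cells)` in absolute value, and the variance of the clipped values
#' is the gene's score. Ties are broken by gene id.
#'
#' @param nm A [normalized_matrix()] (carries the gene/cell universe).
#' @param raw The matching [count_matrix()] the trend is fitted on.
#' @param n Number of genes to return (default 2000, capped at the number
#'   of genes).
#' @param span Loess span of the mean-variance trend.
#' @return Character vector of the top `n` gene ids, ordered by decreasing
#'   standardized variance, with the scores as attribute `"score"`.
#' @export
select_hvgs <- function(nm, raw, n = 2000, span = 0.3) {
  stopifnot(inherits(nm, "NormalizedMatrix"), inherits(raw, "CountMatrix"))
  x <- raw$counts[nm$gene_ids, nm$cell_ids, drop = FALSE]
  n_genes <- nrow(x)
  if (n_genes < 10) ps_stop("fewer than 10 genes; mean-variance trend unfittable")
  if (n > n_genes) ps_stop("n exceeds the number of genes")
  nc <- ncol(x)
  mu <- rowMeans(x)
  v <- apply(x, 1, var)
  usable <- mu > 0 & v > 0
  fit <- loess(log10(v[usable]) ~ log10(mu[usable]), span = span, degree = 2)
  sd_hat <- rep(0, n_genes)
  sd_hat[usable] <- sqrt(10^predict(fit, log10(mu[usable])))
  clip <- sqrt(nc)

  score <- numeric(n_genes)
  for (g in which(usable & sd_hat > 0)) {
    z <- (x[g, ] - mu[g]) / sd_hat[g]
    z <- pmin(pmax(z, -clip), clip)
    score[g] <- var(z)
  }
  names(score) <- rownames(x)
  ord <- order(-score, names(score))
  out <- names(score)[ord][seq_len(n)]
  attr(out, "score") <- score[ord][seq_len(n)]
  out
}

#' Regress out covariates and scale per gene
#'
#' Per gene, computes ordinary least-squares residuals of log-normalized
#' expression on the supplied covariates (with intercept), then centers and
#' standardizes the residuals to unit variance (n-1 denominator). Genes with
#' zero residual variance yield an all-zero row (logged, not an error).
#'
#' @param nm A [normalized_matrix()].
#' @param covariates Data frame or matrix of per-cell covariates (rows =
#'   cells, in `nm` cell order), typically total UMI count and mitochondrial
#'   fraction.
#' @param clip Optional symmetric clipping bound applied after scaling.
#' @return An object of class `ScaledMatrix` with fields `values`,
#'   `gene_ids`, `cell_ids`, `regressed_covariates`, `clip`.
#' @export
regress_scale <- function(nm, covariates = NULL, clip = NULL) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  e <- nm$values
  nc <- ncol(e)
  cov_names <- character()
  if (!is.null(covariates)) {
    cov <- as.matrix(as.data.frame(covariates))
    if (nrow(cov) != nc) ps_stop("covariate table must cover all ", nc, " cells")
    cov_names <- colnames(cov) %||% paste0("cov", seq_len(ncol(cov)))
    x <- cbind(1, cov)
    beta <- e %*% x %*% solve(crossprod(x))
    e <- e - beta %*% t(x)
  } else {
    e <- e - rowMeans(e)
  }
  e <- e - rowMeans(e)  # residuals are centered up to numerical error
  sds <- sqrt(rowSums(e^2) / (nc - 1))
  flat <- sds < 1e-12
  if (any(flat)) {
    ps_log(sum(flat), " gene(s) with zero residual variance scaled to zero")
    e[flat, ] <- 0
  }
  e[!flat, ] <- e[!flat, , drop = FALSE] / sds[!flat]
  if (!is.null(clip)) e <- pmin(pmax(e, -abs(clip)), abs(clip))
  structure(list(values = e, gene_ids = nm$gene_ids, cell_ids = nm$cell_ids,
                 regressed_covariates = cov_names, clip = clip),
            class = "ScaledMatrix")
}

#' Per-cell QC covariates for [regress_scale()]
#'
#' @param m A [count_matrix()].
#' @param mito_genes Character vector of mitochondrial gene ids.
#' @return Data frame with columns `total_umi` and `mito_fraction` (cells in
#'   column order of `m`).
#' @export
cell_covariates <- function(m, mito_genes = character()) {
  stopifnot(inherits(m, "CountMatrix"))
  total <- colSums(m$counts)
  mito_genes <- intersect(mito_genes, m$gene_ids)
  mito <- if (length(mito_genes)) {
    colSums(m$counts[mito_genes, , drop = FALSE]) / pmax(total, 1)
  } else rep(0, length(total))
  data.frame(total_umi = total, mito_fraction = mito, row.names = m$cell_ids)
}
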