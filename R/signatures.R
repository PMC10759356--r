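# Gene-set scoring: mean-expression signatures, binned-control module
# scores, cell-cycle phase assignment, ternary cell-state scores and the
# hormone co-expression quadrant analysis.

present_genes <- function(nm, gs) {
  genes <- intersect(gs$genes, nm$gene_ids)
  dropped <- length(gs$genes) - length(genes)
  if (dropped > 0) ps_log("set '", gs$name, "': ", dropped, " gene(s) absent, dropped")
  if (!length(genes)) ps_stop("no genes of set '", gs$name, "' present in the matrix")
  genes
}

#' Mean-expression signature score
#'
#' Per-cell arithmetic mean of log-normalized expression over the set genes
#' (genes absent from the matrix are dropped with a logged count). This is
#' the signature used for the ternary cell-state analysis; scores are
#' non-negative.
#'
#' @param nm A [normalized_matrix()].
#' @param gs A [gene_set()].
#' @return Data frame with columns `cell_id`, `set_name`, `score`.
#' @export
mean_signature <- function(nm, gs) {
  stopifnot(inherits(nm, "NormalizedMatrix"), inherits(gs, "GeneSet"))
  genes <- present_genes(nm, gs)
  score <- colMeans(nm$values[genes, , drop = FALSE])
  data.frame(cell_id = nm$cell_ids, set_name = gs$name, score = as.numeric(score),
             stringsAsFactors = FALSE)
}

# Equal-frequency expression bins over gene mean expression, ties broken by
# gene id so binning is deterministic.
expression_bins <- function(mean_expr, n_bins) {
  ord <- order(mean_expr, names(mean_expr))
  bin <- integer(length(mean_expr))
  bin[ord] <- ceiling(seq_along(ord) / (length(ord) / n_bins))
  bin[bin > n_bins] <- n_bins
  names(bin) <- names(mean_expr)
  bin
}

#' Binned-control module score
#'
#' All genes are binned into `n_bins` equal-frequency bins by mean
#' expression across cells; for every set gene, `n_ctrl` control genes are
#' drawn with replacement from its bin (seeded). The per-cell score is the
#' mean expression of the set genes minus the mean expression over the
#' pooled control draws, so a random gene set scores ~0 while a
#' coherently up-regulated program scores positive.
#'
#' @param nm A [normalized_matrix()].
#' @param gs A [gene_set()].
#' @param n_bins Number of expression bins (default 24).
#' @param n_ctrl Control draws per set gene (default 100).
#' @param seed Integer seed for the control draws.
#' @return Data frame with columns `cell_id`, `set_name`, `score`.
#' @export
module_score <- function(nm, gs, n_bins = 24, n_ctrl = 100, seed = 1L) {
  stopifnot(inherits(nm, "NormalizedMatrix"), inherits(gs, "GeneSet"), n_bins >= 2)
  genes <- present_genes(nm, gs)
  mean_expr <- rowMeans(nm$values)
  names(mean_expr) <- nm$gene_ids
  bins <- expression_bins(mean_expr, n_bins)

  set.seed(as.integer(seed))
  ctrl <- character(0)
  for (g in genes) {
    pool <- setdiff(names(bins)[bins == bins[[g]]], genes)
    b <- bins[[g]]
    while (!length(pool)) {
      # bin holds only set genes: widen to the nearest non-degenerate bin
      b <- if (b < n_bins) b + 1 else b - 1
      pool <- setdiff(names(bins)[bins == b], genes)
      ps_log("set '", gs$name, "': control bin degenerate for ", g,
             ", using neighboring bin ", b)
    }
    ctrl <- c(ctrl, sample(pool, n_ctrl, replace = TRUE))
  }
  set_mean <- colMeans(nm$values[genes, , drop = FALSE])
  ctrl_mean <- colMeans(nm$values[ctrl, , drop = FALSE])
  data.frame(cell_id = nm$cell_ids, set_name = gs$name,
             score = as.numeric(set_mean - ctrl_mean), stringsAsFactors = FALSE)
}

#' Cell-cycle scoring and phase assignment
#'
#' S and G2/M scores are [module_score()] outputs for the two phase gene
#' sets; a cell is called `G1` when both scores are non-positive, otherwise
#' the phase of the larger score.
#'
#' @param nm A [normalized_matrix()].
#' @param s_set,g2m_set [gene_set()]s for the S and G2/M programs.
#' @param n_bins,n_ctrl,seed Passed to [module_score()].
#' @return Data frame with columns `cell_id`, `s_score`, `g2m_score`,
#'   `phase` (one of `"G1"`, `"S"`, `"G2M"`).
#' @export
cell_cycle_phase <- function(nm, s_set, g2m_set, n_bins = 24, n_ctrl = 100,
                             seed = 1L) {
  s <- module_score(nm, s_set, n_bins, n_ctrl, seed = seed)
  g2m <- module_score(nm, g2m_set, n_bins, n_ctrl, seed = derive_seed(seed, "g2m"))
  phase <- ifelse(s$score <= 0 & g2m$score <= 0, "G1",
                  ifelse(s$score >= g2m$score, "S", "G2M"))
  data.frame(cell_id = nm$cell_ids, s_score = s$score, g2m_score = g2m$score,
             phase = phase, stringsAsFactors = FALSE)
}

#' Ternary cell-state scores
#'
#' Normalizes three non-negative mean-expression signatures (epithelial,
#' mesenchymal, stemness) per cell so they sum to one, placing every cell on
#' the 2-simplex. Cells whose three signatures are all zero receive
#' (1/3, 1/3, 1/3) with a logged count.
#'
#' @param sig_e,sig_m,sig_s Outputs of [mean_signature()] on the same cells
#'   (same order).
#' @return Data frame with columns `cell_id`, `e`, `m`, `s`.
#' @export
ternary_scores <- function(sig_e, sig_m, sig_s) {
  stopifnot(nrow(sig_e) == nrow(sig_m), nrow(sig_m) == nrow(sig_s),
            all(sig_e$cell_id == sig_m$cell_id), all(sig_m$cell_id == sig_s$cell_id))
  mat <- cbind(sig_e$score, sig_m$score, sig_s$score)
  if (any(mat < 0)) {
    ps_stop("negative signature score: ternary scores require mean-expression ",
            "signatures, not module scores")
  }
  tot <- rowSums(mat)
  zero <- tot == 0
  if (any(zero)) ps_log(sum(zero), " cell(s) with all-zero signatures set to (1/3,1/3,1/3)")
  mat[zero, ] <- 1
  tot[zero] <- 3
  mat <- mat / tot
  data.frame(cell_id = sig_e$cell_id, e = mat[, 1], m = mat[, 2], s = mat[, 3],
             stringsAsFactors = FALSE)
}

#' Hormone co-expression quadrant analysis
#'
#' Classifies every cell by the expression of two genes (e.g. *GH1* and
#' *PRL*): a gene is "expressed" when its value exceeds `expr_min` and
#' "high" when it reaches `high_min`. Categories are `neither`, `A_only`,
#' `B_only`, and for double-expressing cells `both_low`, `both_high`,
#' `both_mixed`. Reports per-group category proportions and, separately,
#' the low/high split among double-expressing cells.
#'
#' @param nm A [normalized_matrix()].
#' @param gene_a,gene_b Gene ids (must be present).
#' @param expr_min Detection threshold (exclusive; default 0).
#' @param high_min High-expression threshold (inclusive); default: the
#'   upper-quartile value of each gene over its expressing cells.
#' @param groups Per-cell group labels (e.g. normal / tumor), named by cell
#'   id or in matrix order.
#' @return A list of class `QuadrantSummary` with `category` (per cell),
#'   `proportions` (groups x categories, rows summing to 1) and
#'   `double_expressing` (per group: low vs high fractions among cells
#'   expressing both genes).
#' @export
quadrant_classify <- function(nm, gene_a, gene_b, expr_min = 0, high_min = NULL,
                              groups = NULL) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  for (g in c(gene_a, gene_b)) {
    if (!(g %in% nm$gene_ids)) ps_stop("gene absent from matrix: ", g)
  }
  a <- nm$values[gene_a, ]
  b <- nm$values[gene_b, ]
  if (is.null(groups)) groups <- rep("all", length(a))
  if (!is.null(names(groups))) groups <- groups[nm$cell_ids]
  groups <- as.character(groups)
  stopifnot(length(groups) == length(a))

  high_of <- function(v) {
    expressed <- v[v > expr_min]
    if (!length(expressed)) return(Inf)
    quantile(expressed, 0.75, names = FALSE)
  }
  if (is.null(high_min)) {
    high_a <- high_of(a); high_b <- high_of(b)
  } else {
    stopifnot(high_min > expr_min)
    high_a <- high_min; high_b <- high_min
  }

  ea <- a > expr_min; eb <- b > expr_min
  ha <- a >= high_a; hb <- b >= high_b
  category <- ifelse(!ea & !eb, "neither",
              ifelse(ea & !eb, "A_only",
              ifelse(!ea & eb, "B_only",
              ifelse(ha & hb, "both_high",
              ifelse(!ha & !hb, "both_low", "both_mixed")))))
  cats <- c("neither", "A_only", "B_only", "both_low", "both_high", "both_mixed")
  category <- factor(category, levels = cats)

  props <- t(vapply(split(category, groups), function(cc) {
    as.numeric(table(cc)) / length(cc)
  }, numeric(length(cats))))
  colnames(props) <- cats

  dbl <- t(vapply(split(data.frame(category), groups), function(df) {
    cc <- df$category
    nd <- sum(cc %in% c("both_low", "both_high", "both_mixed"))
    if (nd == 0) return(c(low = NA_real_, high = NA_real_))
    c(low = sum(cc == "both_low") / nd, high = sum(cc == "both_high") / nd)
  }, numeric(2)))

  structure(list(category = stats::setNames(as.character(category), nm$cell_ids),
                 proportions = props, double_expressing = dbl,
                 thresholds = c(expr_min = expr_min, high_a = high_a, high_b = high_b)),
            class = "QuadrantSummary")
}
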