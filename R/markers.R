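# Cluster marker detection: Wilcoxon rank-sum with exact small-sample
# p-values, multiple-testing adjustment, log fold changes, and the two
# filtering regimes (0.25 / adjP 0.01 for cluster markers; 0.75 / adjP 0.05
# for classifier features).

# Exact permutation distribution of the rank sum by dynamic programming over
# doubled midranks (so tied half-integer ranks become integers). Counts the
# number of size-n subsets attaining each possible rank sum; exact for any
# tie pattern.
wilcox_exact_p <- function(r, n) {
  N <- length(r)
  d <- as.integer(round(2 * r))
  S <- sum(d)
  # ways[j+1, s+1] = number of subsets of size j with doubled-rank sum s
  ways <- matrix(0, n + 1, S + 1)
  ways[1, 1] <- 1
  done <- 0
  for (item in d) {
    done <- done + 1
    for (j in seq(min(n, done), 1)) {
      nz <- which(ways[j, ] > 0)
      if (length(nz)) {
        tgt <- nz + item
        ways[j + 1, tgt] <- ways[j + 1, tgt] + ways[j, nz]
      }
    }
  }
  counts <- ways[n + 1, ]
  total <- sum(counts)
  wd <- sum(d[seq_len(n)])
  mu <- n * (N + 1)          # doubled-units mean rank sum: n * sum(d) / N
  dev <- abs(wd - mu)
  sums <- seq_along(counts) - 1
  sum(counts[abs(sums - mu) >= dev - 1e-9]) / total
}

# Tie-corrected normal approximation with continuity correction.
wilcox_normal_p <- function(r, n, m, tie_term = NULL) {
  N <- n + m
  w <- sum(r[seq_len(n)])
  u <- w - n * (n + 1) / 2
  mu <- n * m / 2
  if (is.null(tie_term)) {
    tt <- tabulate(match(r, unique(r)))
    tie_term <- sum(tt^3 - tt)
  }
  sigma2 <- n * m / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-max(z, 0)))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Uses midranks with exact enumeration of the permutation distribution
#' (dynamic programming, exact under any tie pattern) when
#' `n * m <= exact_limit`, and the tie-corrected normal approximation with
#' continuity correction otherwise. Identical pooled values give p = 1.
#'
#' @param x,y Numeric value vectors of the two groups (both non-empty).
#' @param exact_limit Largest `length(x) * length(y)` for which the exact
#'   distribution is enumerated (default 200).
#' @return Two-sided p-value.
#' @export
wilcoxon_test <- function(x, y, exact_limit = 200) {
  n <- length(x); m <- length(y)
  if (n < 1 || m < 1) ps_stop("both groups must be non-empty")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) return(1)
  r <- rank(pooled)
  if (n * m <= exact_limit) wilcox_exact_p(r, n) else wilcox_normal_p(r, n, m)
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up by default; Bonferroni available for
#' compatibility with other marker pipelines.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` or `"bonferroni"`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = method)
}

#' Log2 fold change between two cell groups
#'
#' Computed on de-logged normalized expression:
#' `log2(mean(exp(value) - 1) + pseudo)` of the in-group minus the same for
#' the out-group.
#'
#' @param nm A [normalized_matrix()].
#' @param in_cells,out_cells Disjoint, non-empty cell id (or index) vectors.
#' @param pseudo Pseudo-count (default 1).
#' @param base Fold-change log base, 2 (default) or `exp(1)`.
#' @return Named per-gene vector of log fold changes.
#' @export
log_fold_change <- function(nm, in_cells, out_cells, pseudo = 1, base = 2) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  if (length(intersect(in_cells, out_cells))) ps_stop("groups must be disjoint")
  a <- rowMeans(expm1(nm$values[, in_cells, drop = FALSE]))
  b <- rowMeans(expm1(nm$values[, out_cells, drop = FALSE]))
  (log(a + pseudo) - log(b + pseudo)) / log(base)
}

# Vectorized one-vs-rest rank-sum p-values for all genes at once.
# Ranks and tie terms depend only on the pooled values, so they are
# precomputed once per gene and reused for every cluster.
rank_sum_all_genes <- function(values, in_mask, ranks, tie_terms, exact_limit = 200) {
  n <- sum(in_mask); m <- sum(!in_mask); N <- n + m
  if (n * m <= exact_limit) {
    return(vapply(seq_len(nrow(values)), function(g) {
      wilcoxon_test(values[g, in_mask], values[g, !in_mask], exact_limit)
    }, numeric(1)))
  }
  w <- rowSums(ranks[, in_mask, drop = FALSE])
  u <- w - n * (n + 1) / 2
  mu <- n * m / 2
  sigma2 <- n * m / 12 * ((N + 1) - tie_terms / (N * (N - 1)))
  z <- (abs(u - mu) - 0.5) / sqrt(pmax(sigma2, 1e-300))
  p <- 2 * pnorm(-pmax(z, 0))
  p[sigma2 <= 0] <- 1
  pmin(p, 1)
}

#' Find cluster markers (one-vs-rest)
#'
#' For each cluster, genes passing the detection prefilter (expressed in at
#' least `min_pct` of either group and with absolute log fold change at
#' least `prefilter_lfc`) are tested against all remaining cells with the
#' Wilcoxon rank-sum test; adjusted p-values are computed over the full
#' tested set.
#'
#' @param nm A [normalized_matrix()].
#' @param clusters Per-cell cluster labels (named by cell id, or in `nm`
#'   cell order).
#' @param min_cells Clusters with fewer cells are skipped with a warning.
#' @param min_pct Detection prefilter: minimal expressing fraction in either
#'   group (set 0 to disable).
#' @param prefilter_lfc Minimal absolute log fold change before testing
#'   (set 0 to disable).
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @param only_clusters Optional subset of cluster labels to test.
#' @return A `MarkerTable` data frame with columns `cluster`, `gene`,
#'   `log_fc`, `p_value`, `adj_p`, `pct_in`, `pct_out`.
#' @export
find_markers <- function(nm, clusters, min_cells = 3, min_pct = 0.1,
                         prefilter_lfc = 0.1, adjust = c("BH", "bonferroni"),
                         only_clusters = NULL) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  adjust <- match.arg(adjust)
  if (!is.null(names(clusters))) clusters <- clusters[nm$cell_ids]
  clusters <- as.character(clusters)
  stopifnot(length(clusters) == length(nm$cell_ids))
  sizes <- table(clusters)
  usable <- names(sizes)[sizes >= min_cells]
  skipped <- setdiff(names(sizes), usable)
  if (length(skipped)) {
    warning("cluster(s) below min_cells skipped: ", paste(skipped, collapse = ", "),
            call. = FALSE)
  }
  if (length(usable) < 2) ps_stop("need at least two clusters with >= ", min_cells, " cells")
  test_clusters <- if (is.null(only_clusters)) usable else intersect(only_clusters, usable)

  vals <- nm$values
  expressed <- vals > 0
  n_cells <- ncol(vals)
  large <- n_cells > 40  # ranks reused only on the normal-approximation path
  ranks <- NULL; tie_terms <- NULL
  if (large) {
    ranks <- t(apply(vals, 1, rank))
    tie_terms <- vapply(seq_len(nrow(vals)), function(g) {
      tt <- tabulate(match(vals[g, ], unique(vals[g, ])))
      sum(tt^3 - tt)
    }, numeric(1))
  }

  rows <- list()
  for (cl in test_clusters) {
    in_mask <- clusters == cl
    pct_in <- rowMeans(expressed[, in_mask, drop = FALSE])
    pct_out <- rowMeans(expressed[, !in_mask, drop = FALSE])
    lfc <- log_fold_change(nm, which(in_mask), which(!in_mask))
    keep <- (pmax(pct_in, pct_out) >= min_pct) & (abs(lfc) >= prefilter_lfc)
    if (!any(keep)) next
    sub_vals <- vals[keep, , drop = FALSE]
    p <- rank_sum_all_genes(sub_vals, in_mask,
                            if (large) ranks[keep, , drop = FALSE] else NULL,
                            if (large) tie_terms[keep] else NULL)
    rows[[cl]] <- data.frame(
      cluster = cl, gene = nm$gene_ids[keep], log_fc = lfc[keep],
      p_value = p, adj_p = NA_real_, pct_in = pct_in[keep],
      pct_out = pct_out[keep], stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(tab) || !nrow(tab)) {
    tab <- data.frame(cluster = character(), gene = character(),
                      log_fc = numeric(), p_value = numeric(),
                      adj_p = numeric(), pct_in = numeric(),
                      pct_out = numeric(), stringsAsFactors = FALSE)
  } else {
    tab$adj_p <- bh_adjust(tab$p_value, method = adjust)
  }
  class(tab) <- c("MarkerTable", "data.frame")
  tab
}

#' Filter a marker table by fold change and adjusted p-value
#'
#' Keeps rows with `log_fc > min_log_fc` and `adj_p < max_adj_p` (strict
#' inequalities). The study's cluster-marker regime is
#' `min_log_fc = 0.25, max_adj_p = 0.01`; the classifier-feature regime is
#' `min_log_fc = 0.75, max_adj_p = 0.05`.
#'
#' @param table A `MarkerTable`.
#' @param min_log_fc Minimal log fold change (exclusive).
#' @param max_adj_p Maximal adjusted p-value (exclusive).
#' @param positive_only Additionally require `log_fc > 0`.
#' @return The filtered `MarkerTable`.
#' @export
filter_markers <- function(table, min_log_fc = 0.25, max_adj_p = 0.01,
                           positive_only = TRUE) {
  stopifnot(is.data.frame(table), is.finite(min_log_fc), is.finite(max_adj_p))
  keep <- table$log_fc > min_log_fc & table$adj_p < max_adj_p
  if (positive_only) keep <- keep & table$log_fc > 0
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("MarkerTable", "data.frame")
  out
}
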