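# Single-cell -> bulk aggressiveness transfer: classifier gene selection
# from aggressive-cluster markers, KNN imputation + quantile normalization +
# z-scoring of the bulk cohort, a class-balanced random forest trained on
# cells, and per-sample aggressiveness probabilities.

#' Select classifier genes from an aggressive-cluster marker table
#'
#' Applies the classifier-feature filter (log fold change > `min_log_fc`,
#' adjusted p < `max_adj_p`, positive only) to the aggressive cluster's
#' marker rows, then removes genes not detected in the bulk cohort. Stage
#' counts (tested -> filter-passing -> bulk-detected) are recorded in the
#' selection log.
#'
#' @param table A `MarkerTable` containing the aggressive cluster's rows.
#' @param bulk_genes Character vector of genes present in the bulk cohort.
#' @param cluster Aggressive cluster label (default `"T00"`).
#' @param min_log_fc,max_adj_p Filter thresholds (defaults 0.75 and 0.05).
#' @return Object of class `ClassifierGeneSet`: `genes` (ordered by
#'   decreasing log fold change) and `selection_log` (stage counts and
#'   thresholds).
#' @export
select_classifier_genes <- function(table, bulk_genes, cluster = "T00",
                                    min_log_fc = 0.75, max_adj_p = 0.05) {
  stopifnot(is.data.frame(table))
  rows <- table[table$cluster == cluster, , drop = FALSE]
  if (!nrow(rows)) ps_stop("marker table has no rows for cluster '", cluster, "'")
  n_tested <- nrow(rows)
  filt <- filter_markers(rows, min_log_fc = min_log_fc, max_adj_p = max_adj_p,
                         positive_only = TRUE)
  if (!nrow(filt)) {
    ps_stop("gene selection emptied at the fold-change/adjusted-p filter (",
            n_tested, " genes tested)")
  }
  n_passing <- nrow(filt)
  filt <- filt[order(-filt$log_fc, filt$gene), , drop = FALSE]
  final <- filt$gene[filt$gene %in% bulk_genes]
  if (!length(final)) {
    ps_stop("gene selection emptied at the bulk-detection filter (",
            n_passing, " genes passed thresholds)")
  }
  log <- list(tested = n_tested, passing_filter = n_passing,
              bulk_detected = length(final),
              min_log_fc = min_log_fc, max_adj_p = max_adj_p)
  ps_log("classifier genes: ", n_tested, " tested -> ", n_passing,
         " passing filter -> ", length(final), " detected in bulk")
  structure(list(genes = final, selection_log = log), class = "ClassifierGeneSet")
}

#' K-nearest-neighbor imputation of missing bulk entries
#'
#' Gene-wise KNN: a missing entry of gene g in sample s is imputed as the
#' average over the k genes nearest to g (Euclidean distance computed over
#' the samples where both genes are observed) that are themselves observed
#' in sample s.
#'
#' @param values Samples x genes matrix with `NA` for missing entries.
#' @param k Number of neighbor genes (default 10).
#' @return The matrix with all `NA` entries imputed.
#' @export
impute_knn <- function(values, k = 10) {
  stopifnot(is.matrix(values), k >= 1)
  all_na <- colSums(!is.na(values)) == 0
  if (any(all_na)) {
    ps_stop("gene(s) missing in all samples: ",
            paste(head(colnames(values)[all_na], 5), collapse = ", "))
  }
  miss <- which(is.na(values), arr.ind = TRUE)
  if (!nrow(miss)) return(values)
  out <- values
  for (g in unique(miss[, 2])) {
    # mean squared difference over co-observed samples, per candidate gene
    dists <- vapply(seq_len(ncol(values)), function(h) {
      if (h == g) return(Inf)
      both <- !is.na(values[, g]) & !is.na(values[, h])
      if (!any(both)) return(Inf)
      mean((values[both, g] - values[both, h])^2)
    }, numeric(1))
    ord <- order(dists)
    for (s in miss[miss[, 2] == g, 1]) {
      nbr <- ord[is.finite(dists[ord]) & !is.na(values[s, ord])]
      nbr <- nbr[seq_len(min(k, length(nbr)))]
      if (!length(nbr)) {
        out[s, g] <- mean(values[, g], na.rm = TRUE)  # fallback: gene mean
      } else {
        out[s, g] <- mean(values[s, nbr])
      }
    }
  }
  out
}

#' Quantile normalization across samples
#'
#' Forces every sample (row) to share an identical value distribution:
#' sorted values are replaced by the rank-wise mean of sorted values over
#' all samples; tied ranks receive the mean of the corresponding reference
#' quantiles.
#'
#' @param values Samples x genes matrix without missing entries.
#' @return The quantile-normalized matrix.
#' @export
quantile_normalize <- function(values) {
  stopifnot(is.matrix(values), !anyNA(values))
  out <- t(limma::normalizeQuantiles(t(values), ties = TRUE))
  dimnames(out) <- dimnames(values)
  out
}

# per-column z-scores with n-1 denominator; constant columns -> zero
zscore_columns <- function(values, what = "column") {
  mu <- colMeans(values)
  sds <- apply(values, 2, sd)
  flat <- sds < 1e-12
  if (any(flat)) ps_log(sum(flat), " constant ", what, "(s) z-scored to zero")
  sds[flat] <- 1
  out <- sweep(sweep(values, 2, mu), 2, sds, "/")
  out[, flat] <- 0
  out
}

#' Harmonize a bulk cohort onto the classifier feature scale
#'
#' Chains the bulk-side reconciliation on the full cohort: (1) KNN
#' imputation of missing entries, (2) quantile normalization across
#' samples, (3) per-gene z-scoring (n-1 denominator); the selected genes
#' are extracted last. Normalizing over the whole gene universe matters: on
#' the selected genes alone, a genuinely elevated sample would be flattened
#' by quantile normalization, since all its features would shift together.
#'
#' @param cohort A [bulk_cohort()].
#' @param genes A `ClassifierGeneSet` (or character vector); all genes must
#'   be present in the cohort and observed in at least 2 samples.
#' @param k_impute Neighbors for [impute_knn()] (default 10).
#' @return Samples x genes matrix of z-scores, columns in selection order.
#' @export
harmonize_bulk <- function(cohort, genes, k_impute = 10) {
  stopifnot(inherits(cohort, "BulkCohort"))
  gg <- if (inherits(genes, "ClassifierGeneSet")) genes$genes else as.character(genes)
  absent <- setdiff(gg, cohort$gene_ids)
  if (length(absent)) {
    ps_stop("selected gene(s) absent from the cohort: ",
            paste(head(absent, 5), collapse = ", "))
  }
  x <- cohort$values
  thin <- colSums(!is.na(x[, gg, drop = FALSE])) < 2
  if (any(thin)) {
    ps_stop("gene(s) observed in fewer than 2 samples: ",
            paste(head(gg[thin], 5), collapse = ", "))
  }
  x <- impute_knn(x, k = k_impute)
  x <- quantile_normalize(x)
  zscore_columns(x, "gene")[, gg, drop = FALSE]
}

#' Z-score single-cell expression for the classifier
#'
#' Per-gene z-scores of log-normalized expression over cells (n-1
#' denominator); constant genes give a zero column (logged).
#'
#' @param nm A [normalized_matrix()].
#' @param genes A `ClassifierGeneSet` or character vector of genes present
#'   in the matrix.
#' @return Cells x genes matrix of z-scores.
#' @export
harmonize_sc <- function(nm, genes) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  gg <- if (inherits(genes, "ClassifierGeneSet")) genes$genes else as.character(genes)
  absent <- setdiff(gg, nm$gene_ids)
  if (length(absent)) {
    ps_stop("gene(s) absent from the matrix: ", paste(head(absent, 5), collapse = ", "))
  }
  zscore_columns(t(nm$values[gg, , drop = FALSE]), "gene")
}

#' Train the class-balanced aggressiveness random forest
#'
#' Fits a random forest on per-cell z-scored features with stratified
#' per-tree sampling: each tree draws `n_pos` aggressive and `n_neg`
#' non-aggressive cells with replacement (`sampsize`/`strata` in the
#' underlying implementation), `sqrt(p)` candidate features per split, and
#' unpruned trees. Defaults follow the published configuration: 4000 trees,
#' 1500 aggressive vs 500 non-aggressive per tree.
#'
#' @param features Cells x genes matrix of z-scores.
#' @param labels Per-cell labels, `"aggressive"` / `"non_aggressive"` (both
#'   classes must be present).
#' @param n_trees Number of trees (default 4000).
#' @param n_pos,n_neg Per-tree stratified sample sizes (defaults 1500/500).
#' @param seed Integer seed; training is deterministic under it.
#' @return Object of class `EnsembleModel` wrapping the fitted forest with
#'   its feature order and sampling specification.
#' @export
train_classifier <- function(features, labels, n_trees = 4000,
                             n_pos = 1500, n_neg = 500, seed = 1L) {
  stopifnot(is.matrix(features), nrow(features) == length(labels),
            n_pos >= 1, n_neg >= 1)
  labels <- factor(as.character(labels), levels = c("aggressive", "non_aggressive"))
  if (any(is.na(labels))) ps_stop("labels must be 'aggressive' or 'non_aggressive'")
  if (nlevels(droplevels(labels)) < 2) ps_stop("both classes must be present")
  # per-tree stratum sizes cannot exceed the class frequencies
  counts <- table(labels)
  eff_pos <- min(n_pos, counts[["aggressive"]])
  eff_neg <- min(n_neg, counts[["non_aggressive"]])
  if (eff_pos < n_pos || eff_neg < n_neg) {
    ps_log("stratified sample sizes capped at class frequencies: ",
           eff_pos, " aggressive / ", eff_neg, " non-aggressive per tree")
  }
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(
    x = features, y = labels, ntree = n_trees,
    strata = labels,
    sampsize = c(aggressive = eff_pos, non_aggressive = eff_neg),
    replace = TRUE)
  structure(list(forest = rf, feature_names = colnames(features),
                 n_trees = n_trees, n_pos = n_pos, n_neg = n_neg,
                 seed = as.integer(seed)),
            class = "EnsembleModel")
}

#' Score bulk samples for aggressiveness
#'
#' Applies the trained ensemble to harmonized bulk features; the
#' probability of the aggressive class is the fraction of trees voting
#' aggressive. Samples are ranked by decreasing probability (ties broken by
#' sample id order). The feature columns must match the model's feature
#' order exactly; mismatches are an error, never silently reordered.
#'
#' @param model An `EnsembleModel` from [train_classifier()].
#' @param bulk_features Samples x genes matrix of z-scores (from
#'   [harmonize_bulk()]).
#' @return Data frame with columns `sample_id`, `p_aggressive`,
#'   `p_non_aggressive`, `rank`.
#' @export
predict_aggressiveness <- function(model, bulk_features) {
  stopifnot(inherits(model, "EnsembleModel"), is.matrix(bulk_features))
  if (!identical(colnames(bulk_features), model$feature_names)) {
    ps_stop("bulk feature columns do not match the model's feature order")
  }
  prob <- predict(model$forest, newdata = bulk_features, type = "prob")
  p_aggr <- as.numeric(prob[, "aggressive"])
  ids <- rownames(bulk_features) %||% as.character(seq_len(nrow(bulk_features)))
  ord <- order(-p_aggr, ids)
  rk <- integer(length(ord))
  rk[ord] <- seq_along(ord)
  data.frame(sample_id = ids, p_aggressive = p_aggr,
             p_non_aggressive = 1 - p_aggr, rank = rk,
             stringsAsFactors = FALSE)
}
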