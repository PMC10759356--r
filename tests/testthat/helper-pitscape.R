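options(pitscape.quiet = TRUE)

# wrap a bare matrix of log-normalized values
make_nm <- function(values, genes = NULL, cells = NULL) {
  genes <- genes %||% sprintf("g%03d", seq_len(nrow(values)))
  cells <- cells %||% sprintf("c%03d", seq_len(ncol(values)))
  normalized_matrix(values, genes, cells)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracle: exhaustive enumeration of the two-sided rank-sum
# permutation p-value over all C(N, n) group assignments (handles ties via
# midranks). Used to validate wilcoxon_test, never to implement it.
wilcox_oracle <- function(x, y) {
  n <- length(x)
  N <- n + length(y)
  r <- rank(c(x, y))
  mu <- n * (N + 1) / 2
  obs <- abs(sum(r[seq_len(n)]) - mu)
  combs <- utils::combn(N, n)
  ws <- colSums(matrix(r[combs], nrow = n))
  mean(abs(ws - mu) >= obs - 1e-9)
}

# Independent step-up computation of Benjamini-Hochberg adjusted p-values.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  q
}

# matched hormone regimes across clusters -> exchangeable null data
null_regimes <- function(labels) {
  stats::setNames(rep("both-low", length(labels)), labels)
}

# rank-1 bulk matrix whose gene profiles come in identical replicate blocks,
# so gene-wise KNN neighbors are exact copies (imputable without error even
# when a few copies are co-masked at the same sample)
replicated_rank1 <- function(n_samples = 13, n_blocks = 3, block_size = 16,
                             seed = 1) {
  set.seed(seed)
  a <- runif(n_samples, 1, 3)
  b <- rep(runif(n_blocks, 0.5, 4), each = block_size)
  vals <- outer(a, b)
  dimnames(vals) <- list(sprintf("s%02d", seq_len(n_samples)),
                         sprintf("g%03d", seq_along(b)))
  vals
}

run_transfer <- function(seed, n_trees = 500) {
  sim <- generate_sc_dataset(n_genes = 800, n_cells = 1000,
                             clusters = c(T01 = 0.5, T02 = 0.5),
                             aggressive_fraction = 0.03,
                             seed = derive_seed(seed, "sc"))
  nm <- lognormalize(sim$counts)
  cl <- stats::setNames(sim$annotation$cluster, sim$annotation$cell_id)
  mk <- suppressWarnings(find_markers(nm, cl, only_clusters = "T00"))
  cent <- compute_centroids(nm, cl)
  bulk <- generate_bulk_cohort(sim$truth, cent, seed = derive_seed(seed, "bulk"))
  genes <- select_classifier_genes(mk, bulk$gene_ids)
  scf <- harmonize_sc(nm, genes)
  bkf <- harmonize_bulk(bulk, genes)
  labels <- ifelse(rownames(scf) %in% sim$truth$aggressive_cells,
                   "aggressive", "non_aggressive")
  model <- train_classifier(scf, labels, n_trees = n_trees,
                            seed = derive_seed(seed, "rf"))
  pred <- predict_aggressiveness(model, bkf)
  carc <- bulk$labels == "carcinoma_like"
  auc <- (sum(rank(pred$p_aggressive)[carc]) - sum(carc) * (sum(carc) + 1) / 2) /
    (sum(carc) * sum(!carc))
  list(pred = pred, carcinoma = carc, auc = auc,
       top3 = all(rank(-pred$p_aggressive, ties.method = "min")[carc] <= 3))
}
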