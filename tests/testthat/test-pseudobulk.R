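test_that("pseudo-bulk profiles are exact gene-wise sums (linear, additive)", {
  set.seed(21)
  v <- matrix(runif(30 * 6, 0, 3), 30, 6)
  nm <- make_nm(v)
  pb <- build_pseudobulk(nm, c("s1", "s1", "s2", "s2", "s2", "s3"))
  ids <- vapply(pb, function(p) p$sample_id, "")
  expect_equal(unname(pb[[match("s3", ids)]]$summed_expression), v[, 6])
  expect_equal(unname(pb[[match("s1", ids)]]$summed_expression), rowSums(v[, 1:2]))

  # duplicating every cell doubles the profile
  nm2 <- make_nm(cbind(v, v), cells = sprintf("c%02d", 1:12))
  pb2 <- build_pseudobulk(nm2, rep(c("s1", "s1", "s2", "s2", "s2", "s3"), 2))
  expect_equal(pb2[[match("s1", ids)]]$summed_expression,
               2 * pb[[match("s1", ids)]]$summed_expression)

  # splitting a sample then summing equals the unsplit profile
  pb3 <- build_pseudobulk(nm, c("x1", "x2", "s2", "s2", "s2", "s3"))
  ids3 <- vapply(pb3, function(p) p$sample_id, "")
  expect_equal(pb3[[match("x1", ids3)]]$summed_expression +
                 pb3[[match("x2", ids3)]]$summed_expression,
               pb[[match("s1", ids)]]$summed_expression)
})

test_that("PC embedding captures rank-1 structure and preserves distances at full rank", {
  set.seed(30)
  direction <- runif(40)
  weights <- seq(-2, 2, length.out = 8)
  x <- outer(weights, direction) + 5
  rownames(x) <- paste0("o", 1:8)
  emb <- pc_embed(x, n_pcs = 3, scale = FALSE)
  tot <- attr(emb, "sdev")^2
  expect_gt(tot[1] / sum(tot), 1 - 1e-9)
  expect_lt(max(abs(emb[, 2:3])), 1e-8)

  y <- matrix(rnorm(8 * 40), 8, 40, dimnames = list(paste0("o", 1:8), NULL))
  embf <- pc_embed(y, n_pcs = 7, scale = TRUE)
  d_emb <- dist(embf)
  d_raw <- dist(scale(y))
  expect_equal(as.numeric(d_emb), as.numeric(d_raw), tolerance = 1e-8)

  # permutation equivariance
  perm <- c(3, 1, 2, 8, 7, 4, 5, 6)
  embp <- pc_embed(y[perm, ], n_pcs = 7, scale = TRUE)
  expect_equal(matrix(embp, nrow(embp)), matrix(embf[perm, ], nrow(embp)),
               tolerance = 1e-8)

  expect_error(pc_embed(y[1, , drop = FALSE], n_pcs = 1), "two observations")
  expect_error(pc_embed(y, n_pcs = 8), "n_pcs")
})

test_that("cosine similarity obeys its geometric identities", {
  u <- c(1, 2, 3)
  coords <- rbind(a = u, b = 2 * u, c = c(3, 0, -1), d = -u, e = c(0, 0, 0))
  s <- cosine_similarity_matrix(coords)
  expect_equal(s$values["a", "b"], 1, tolerance = 1e-12)
  expect_equal(s$values["a", "c"], 0, tolerance = 1e-12)
  expect_equal(s$values["a", "d"], -1, tolerance = 1e-12)
  expect_equal(s$values["a", "e"], 0)
  expect_equal(unname(diag(s$values)), rep(1, 5))
  expect_equal(s$values, t(s$values))

  # invariance to a sign flip of any axis applied to all observations
  flipped <- coords %*% diag(c(1, -1, 1))
  s2 <- cosine_similarity_matrix(flipped)
  expect_equal(unname(s$values), unname(s2$values), tolerance = 1e-12)
})

test_that("within-lineage pseudo-bulk similarity exceeds between-lineage similarity", {
  for (seed in c(101, 202, 303)) {
    w <- rbind(matrix(rep(c(.4, .4, .1, .05, .05), 4), 4, byrow = TRUE),
               matrix(rep(c(.05, .05, .1, .4, .4), 4), 4, byrow = TRUE))
    sim <- generate_sc_dataset(n_genes = 600, n_cells = 1200,
                               clusters = c(C1 = .2, C2 = .2, C3 = .2,
                                            C4 = .2, C5 = .2),
                               de_fraction = 0.05, de_effect = 2,
                               aggressive_fraction = 0, n_samples = 8,
                               sample_cluster_weights = w, seed = seed)
    nm <- lognormalize(sim$counts)
    pb <- build_pseudobulk(nm, stats::setNames(sim$annotation$sample_id,
                                               sim$annotation$cell_id))
    coords <- pc_embed(pb, n_pcs = 5)
    s <- cosine_similarity_matrix(coords)$values
    lineage <- rep(c(1, 2), each = 4)
    same <- outer(lineage, lineage, "==") & upper.tri(s)
    diff <- outer(lineage, lineage, "!=") & upper.tri(s)
    expect_gt(mean(s[same]), mean(s[diff]))
  }
})

test_that("the dendrogram merges nearest clusters first and splits planted lineages", {
  # three centroids at pairwise distances (1, 1ish, 10ish): nearest pair first
  set.seed(40)
  cells <- cbind(matrix(rep(c(0, 0), 10), 2), matrix(rep(c(1, 0), 10), 2),
                 matrix(rep(c(10, 0), 10), 2))
  cells <- cells + rnorm(length(cells), sd = 1e-3)
  dimnames(cells) <- list(c("TF1", "TF2"), sprintf("c%02d", 1:30))
  sm <- structure(list(values = cells,
                       gene_ids = c("TF1", "TF2"),
                       cell_ids = sprintf("c%02d", 1:30),
                       regressed_covariates = character(), clip = NULL),
                  class = "ScaledMatrix")
  cl <- rep(c("near1", "near2", "far"), each = 10)
  dres <- cluster_dendrogram(sm, cl, tf_genes = c("TF1", "TF2"), n_pcs = 2)
  first <- dres$hclust$merge[1, ]
  expect_setequal(dres$labels[-first], c("near1", "near2"))
  expect_lt(dres$hclust$height[1], dres$hclust$height[2])
  expect_match(dres$newick, "far")

  # duplicated cluster (identical cells relabeled) merges at height 0
  sm2 <- sm
  cl2 <- c(rep(c("a", "a2"), each = 5), rep("b", 10), rep("c", 10))
  dres2 <- cluster_dendrogram(sm2, cl2, c("TF1", "TF2"), n_pcs = 2)
  expect_lt(dres2$hclust$height[1], 1e-2)
  expect_setequal(dres2$labels[-dres2$hclust$merge[1, ]], c("a", "a2"))

  expect_error(cluster_dendrogram(sm, rep("one", 30), c("TF1", "TF2")), "two clusters")
  expect_error(cluster_dendrogram(sm, cl, c("notagene")), "transcription-factor")
})

test_that("lineage-sharing clusters bipartition in the TF dendrogram", {
  sim <- generate_sc_dataset(n_genes = 400, n_cells = 800,
                             clusters = c(A = .25, B = .25, C = .25, D = .25),
                             de_fraction = 0.05, de_effect = 2,
                             aggressive_fraction = 0, seed = 50)
  # shared lineage programs: A/B express each other's DE block at half strength
  x <- sim$counts$counts
  cl <- sim$truth$cluster_of_cell[sim$counts$cell_ids]
  boost <- function(x, genes, cells) {
    x[genes, cells] <- x[genes, cells] + matrix(
      rpois(length(genes) * sum(cells), 3), length(genes))
    x
  }
  x <- boost(x, sim$truth$de_genes$A$gene, cl == "B")
  x <- boost(x, sim$truth$de_genes$B$gene, cl == "A")
  x <- boost(x, sim$truth$de_genes$C$gene, cl == "D")
  x <- boost(x, sim$truth$de_genes$D$gene, cl == "C")
  nm <- lognormalize(count_matrix(x, sim$counts$gene_ids, sim$counts$cell_ids))
  sm <- regress_scale(nm)
  tf <- unlist(lapply(sim$truth$de_genes, function(d) d$gene), use.names = FALSE)
  dres <- cluster_dendrogram(sm, cl, tf, n_pcs = 10)
  # the last merge joins {A,B} with {C,D}
  cut2 <- stats::cutree(dres$hclust, k = 2)
  expect_equal(cut2[["A"]], cut2[["B"]])
  expect_equal(cut2[["C"]], cut2[["D"]])
  expect_false(cut2[["A"]] == cut2[["C"]])
})
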