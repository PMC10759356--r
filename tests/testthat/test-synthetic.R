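test_that("the generator is fully deterministic under a fixed seed", {
  a <- generate_sc_dataset(n_genes = 300, n_cells = 200, seed = 99)
  b <- generate_sc_dataset(n_genes = 300, n_cells = 200, seed = 99)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$cluster_of_cell, b$truth$cluster_of_cell)
  c <- generate_sc_dataset(n_genes = 300, n_cells = 200, seed = 100)
  expect_false(identical(a$counts$counts, c$counts$counts))
})

test_that("cluster composition is apportioned exactly and aggressive cells span all samples", {
  sim <- generate_sc_dataset(n_genes = 400, n_cells = 1000,
                             clusters = c(T01 = 0.3, T02 = 0.3, T03 = 0.4),
                             aggressive_fraction = 0.02, n_samples = 4, seed = 5)
  tab <- table(sim$annotation$cluster)
  expect_equal(as.integer(tab[c("T01", "T02", "T03")]), c(294L, 294L, 392L))
  expect_equal(as.integer(tab["T00"]), 20L)
  aggr <- sim$annotation[sim$annotation$cluster == "T00", ]
  expect_setequal(unique(aggr$sample_id), unique(sim$annotation$sample_id))
  expect_setequal(sim$truth$aggressive_cells, aggr$cell_id)
})

test_that("empirical per-cluster means converge to the planted programs", {
  sim <- generate_sc_dataset(n_genes = 400, n_cells = 4000,
                             clusters = c(A = 0.5, B = 0.5),
                             de_fraction = 0.05, de_effect = 1,
                             libsize_sigma = 0, aggressive_fraction = 0,
                             hormone_regimes = null_regimes(c("A", "B")),
                             seed = 17)
  x <- sim$counts$counts
  inA <- sim$truth$cluster_of_cell[sim$counts$cell_ids] == "A"
  de_a <- sim$truth$de_genes$A$gene
  ratio <- rowMeans(x[de_a, inA]) / rowMeans(x[de_a, !inA])
  # planted log2 effect of 1 -> mean ratio 2 within sampling tolerance
  expect_equal(mean(ratio), 2, tolerance = 0.05)
  bg <- grep("^G", sim$counts$gene_ids, value = TRUE)[1:100]
  ratio_bg <- rowMeans(x[bg, inA]) / rowMeans(x[bg, !inA])
  expect_equal(mean(ratio_bg), 1, tolerance = 0.05)
})

test_that("a null configuration carries no planted signal", {
  sim <- generate_sc_dataset(n_genes = 500, n_cells = 400,
                             clusters = c(A = 0.5, B = 0.5), de_effect = 0,
                             aggressive_fraction = 0,
                             hormone_regimes = null_regimes(c("A", "B")),
                             seed = 23)
  nm <- lognormalize(sim$counts)
  cl <- stats::setNames(sim$annotation$cluster, sim$annotation$cell_id)
  mk <- find_markers(nm, cl, min_pct = 0, prefilter_lfc = 0, only_clusters = "A")
  expect_lt(mean(mk$p_value < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(mk)))
})

test_that("degenerate bulk mixtures reproduce the centroid exactly", {
  sim <- generate_sc_dataset(n_genes = 200, n_cells = 300,
                             clusters = c(T01 = 1), aggressive_fraction = 0.05,
                             seed = 7)
  nm <- lognormalize(sim$counts)
  cent <- compute_centroids(nm, stats::setNames(sim$annotation$cluster,
                                                sim$annotation$cell_id))
  bulk <- generate_bulk_cohort(sim$truth, cent, n_samples = 4,
                               carcinoma_aggressive_weight = 0,
                               base_aggressive_weight = 0,
                               n_carcinoma = 1, n_invasive = 1,
                               noise_sigma = 0, na_rate = 0,
                               bulk_gene_fraction = 1, seed = 8)
  c_t01 <- cent[[which(vapply(cent, function(x) x$cluster, "") == "T01")]]
  for (s in seq_len(4)) {
    expect_equal(unname(bulk$values[s, ]), unname(c_t01$mean_expression),
                 tolerance = 1e-12)
  }
})

test_that("bulk cohorts record labels and valid mixing weights; na_rate 1 fails", {
  sim <- generate_sc_dataset(n_genes = 200, n_cells = 300,
                             aggressive_fraction = 0.05, seed = 7)
  nm <- lognormalize(sim$counts)
  cent <- compute_centroids(nm, stats::setNames(sim$annotation$cluster,
                                                sim$annotation$cell_id))
  bulk <- generate_bulk_cohort(sim$truth, cent, seed = 9)
  expect_equal(table(bulk$labels)[["carcinoma_like"]], 3L)
  expect_equal(unname(rowSums(bulk$mixing_weights)), rep(1, 13), tolerance = 1e-12)
  expect_true(all(bulk$mixing_weights >= 0))
  expect_equal(unname(bulk$mixing_weights[1:3, "T00"]), rep(0.4, 3))
  expect_error(generate_bulk_cohort(sim$truth, cent, na_rate = 1, seed = 9),
               "na_rate")
})

test_that("reference atlases share the requested gene fraction and degrade gracefully", {
  sim <- generate_sc_dataset(n_genes = 300, n_cells = 400,
                             clusters = c(A = 0.5, B = 0.5),
                             aggressive_fraction = 0, seed = 3)
  nm <- lognormalize(sim$counts)
  cent <- compute_centroids(nm, stats::setNames(sim$annotation$cluster,
                                                sim$annotation$cell_id))
  atlas <- generate_reference_atlas(cent, gene_keep_fraction = 0.8, seed = 4)
  expect_equal(length(atlas$expression$gene_ids), round(0.8 * 300))
  expect_true(all(atlas$expression$gene_ids %in% nm$gene_ids))
  expect_error(generate_reference_atlas(cent, gene_keep_fraction = 0.1, seed = 4),
               "50")

  # noiseless configuration: every atlas cell equals its source centroid
  atlas0 <- generate_reference_atlas(cent, gene_keep_fraction = 1,
                                     scale_sigma = 0, cell_noise_sd = 0, seed = 4)
  cm <- vapply(cent, function(x) x$mean_expression, numeric(300))
  colnames(cm) <- vapply(cent, function(x) x$cluster, "")
  for (i in seq_along(atlas0$expression$cell_ids)) {
    cl <- atlas0$annotation$cluster[i]
    expect_equal(unname(atlas0$expression$values[, i]), unname(cm[, cl]),
                 tolerance = 1e-12)
  }
})
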