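# Synthetic data with recorded ground truth.  The generator emulates the
# statistical structure of a PitNET-style single-cell study: clustered
# negative-binomial counts with hormone-gene programs, a small cross-sample
# aggressive subpopulation carrying an up-regulated proliferation program,
# a mitochondrial gene block and variable library sizes; bulk cohorts as
# noisy mixtures of cluster centroids; and a perturbed reference atlas.

HORMONE_GENES <- c("HORM-A", "HORM-B")
AGGRESSIVE_CLUSTER <- "T00"
HORMONE_REGIMES <- c("both-low", "both-high", "A-only", "B-only", "neither")

hormone_regime_means <- function(regime, low, high, off) {
  switch(regime,
    "both-low"  = c(low, low),
    "both-high" = c(high, high),
    "A-only"    = c(high, off),
    "B-only"    = c(off, high),
    "neither"   = c(off, off),
    ps_stop("unknown hormone regime: ", regime))
}

rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Generate a clustered single-cell count dataset with known ground truth
#'
#' Counts follow a negative-binomial model: per-gene baseline means are
#' log-normal, multiplied by a cluster-specific fold for planted
#' differentially expressed (DE) genes, by a per-cell log-normal library-size
#' factor, and overdispersed with a common dispersion. A designated hormone
#' gene pair (`HORM-A`, `HORM-B`) follows a per-cluster regime from
#' both-low / both-high / A-only / B-only / neither; a designated block of
#' mitochondrial genes (ids prefixed `MT-`) and a proliferation program are
#' reserved. A small fraction of cells, spread across every sample, form the
#' aggressive cluster `"T00"` whose proliferation-program genes are
#' up-shifted.
#'
#' @param n_genes,n_cells Dataset dimensions.
#' @param clusters Named numeric vector of cluster proportions (names are
#'   cluster labels; must sum to 1). Do not include `"T00"`; the aggressive
#'   cluster is carved out by `aggressive_fraction`.
#' @param de_fraction Fraction of genes planted as DE per cluster.
#' @param de_effect Planted log2 mean shift of DE genes in their cluster.
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param libsize_sigma Standard deviation of the log-normal library-size
#'   factor.
#' @param mito_fraction Fraction of genes designated mitochondrial.
#' @param aggressive_fraction Fraction of cells planted as aggressive.
#' @param proliferation_set_size Number of proliferation-program genes.
#' @param prolif_effect Log2 up-shift of proliferation genes in aggressive
#'   cells.
#' @param n_samples Number of samples the cells are distributed over.
#' @param sample_groups Optional character vector (length `n_samples`) of
#'   `"normal"`/`"tumor"` labels; default all tumor.
#' @param sample_cluster_weights Optional `n_samples` x `n_clusters` matrix:
#'   how each cluster's cells are apportioned over samples (columns are
#'   normalized). Default: balanced round-robin.
#' @param hormone_regimes Optional named character vector cluster -> regime;
#'   default cycles through the five regimes in cluster order, `"T00"`
#'   getting `"neither"`.
#' @param hormone_low_mean,hormone_high_mean,hormone_off_mean Mean counts of
#'   a hormone gene under the low / high / off expression state.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A list with elements `counts` ([count_matrix()]), `annotation`
#'   ([cell_annotation()]) and `truth` (class `SyntheticTruth`: cluster,
#'   sample, and aggressive-cell assignments, planted DE genes and effects,
#'   hormone/mito/proliferation gene ids and regimes, seed, parameters).
#' @export
generate_sc_dataset <- function(n_genes = 2000, n_cells = 3000,
                                clusters = c(T01 = 0.5, T02 = 0.5),
                                de_fraction = 0.05, de_effect = 2,
                                dispersion = 0.1, libsize_sigma = 0.3,
                                mito_fraction = 0.05,
                                aggressive_fraction = 0.02,
                                proliferation_set_size = 50,
                                prolif_effect = 2,
                                n_samples = 4,
                                sample_groups = NULL,
                                sample_cluster_weights = NULL,
                                hormone_regimes = NULL,
                                hormone_low_mean = 20,
                                hormone_high_mean = 400,
                                hormone_off_mean = 0.05,
                                seed = 1L) {
  k <- length(clusters)
  stopifnot(k >= 1, !is.null(names(clusters)), n_cells >= k)
  if (abs(sum(clusters) - 1) > 1e-8) ps_stop("cluster proportions must sum to 1")
  if (de_fraction < 0 || de_fraction > 1 || aggressive_fraction < 0 ||
      aggressive_fraction > 1 || mito_fraction < 0 || mito_fraction > 1) {
    ps_stop("fractions must lie in [0, 1]")
  }
  if (AGGRESSIVE_CLUSTER %in% names(clusters)) {
    ps_stop("'", AGGRESSIVE_CLUSTER, "' is reserved for the aggressive cluster")
  }
  n_de <- round(de_fraction * n_genes)
  if (de_fraction > 0 && n_de < 1) {
    ps_stop("infeasible configuration: de_fraction x n_genes < 1")
  }
  n_mito <- round(mito_fraction * n_genes)
  n_aggr <- round(aggressive_fraction * n_cells)
  n_prolif <- if (n_aggr > 0) proliferation_set_size else proliferation_set_size
  reserved <- n_mito + 2 + n_prolif + k * n_de
  if (reserved > n_genes) {
    ps_stop("infeasible configuration: ", reserved,
            " reserved genes exceed n_genes = ", n_genes)
  }

  set.seed(as.integer(seed))

  # --- gene layout -----------------------------------------------------
  mito_genes <- if (n_mito) sprintf("MT-%04d", seq_len(n_mito)) else character()
  prolif_genes <- if (n_prolif) sprintf("PROLIF-%03d", seq_len(n_prolif)) else character()
  de_genes <- lapply(seq_len(k), function(i) {
    if (n_de) sprintf("DE-%s-%03d", names(clusters)[i], seq_len(n_de)) else character()
  })
  names(de_genes) <- names(clusters)
  n_bg <- n_genes - reserved
  bg_genes <- if (n_bg) sprintf("G%05d", seq_len(n_bg)) else character()
  gene_ids <- c(mito_genes, HORMONE_GENES, prolif_genes,
                unlist(de_genes, use.names = FALSE), bg_genes)

  # --- per-gene baselines ----------------------------------------------
  base_mean <- rlnorm(n_genes, meanlog = 0, sdlog = 1)
  names(base_mean) <- gene_ids
  # proliferation markers are moderately expressed genes (PTTG1/TOP2A-like)
  base_mean[prolif_genes] <- rlnorm(n_prolif, meanlog = 1, sdlog = 0.5)

  # --- cluster structure -----------------------------------------------
  all_clusters <- c(names(clusters), if (n_aggr) AGGRESSIVE_CLUSTER)
  if (is.null(hormone_regimes)) {
    hormone_regimes <- stats::setNames(
      HORMONE_REGIMES[(seq_along(names(clusters)) - 1) %% 5 + 1], names(clusters))
    if (n_aggr) hormone_regimes[AGGRESSIVE_CLUSTER] <- "neither"
  } else {
    missing_k <- setdiff(all_clusters, names(hormone_regimes))
    if (length(missing_k)) {
      hormone_regimes[missing_k] <- "neither"
    }
  }

  fold <- matrix(1, n_genes, length(all_clusters),
                 dimnames = list(gene_ids, all_clusters))
  for (cl in names(clusters)) fold[de_genes[[cl]], cl] <- 2^de_effect
  if (n_aggr) fold[prolif_genes, AGGRESSIVE_CLUSTER] <- 2^prolif_effect

  # --- cell assignment (deterministic largest-remainder apportionment) --
  n_base <- n_cells - n_aggr
  cells_per_cluster <- apportion(n_base, as.numeric(clusters))
  cluster_of_cell <- c(rep(names(clusters), cells_per_cluster),
                       rep(AGGRESSIVE_CLUSTER, n_aggr))
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  names(cluster_of_cell) <- cell_ids

  sample_ids <- sprintf("S%02d", seq_len(n_samples))
  if (is.null(sample_groups)) sample_groups <- rep("tumor", n_samples)
  stopifnot(length(sample_groups) == n_samples)
  sample_of_cell <- character(n_cells)
  for (cl in all_clusters) {
    idx <- which(cluster_of_cell == cl)
    if (!length(idx)) next
    if (is.null(sample_cluster_weights) || cl == AGGRESSIVE_CLUSTER) {
      sample_of_cell[idx] <- sample_ids[(seq_along(idx) - 1) %% n_samples + 1]
    } else {
      w <- sample_cluster_weights[, match(cl, names(clusters))]
      counts_s <- apportion(length(idx), w / sum(w))
      sample_of_cell[idx] <- rep(sample_ids, counts_s)
    }
  }
  names(sample_of_cell) <- cell_ids

  # --- draw counts ------------------------------------------------------
  lib <- rlnorm(n_cells, meanlog = 0, sdlog = libsize_sigma)
  counts <- matrix(0, n_genes, n_cells, dimnames = list(gene_ids, cell_ids))
  for (cl in all_clusters) {
    idx <- which(cluster_of_cell == cl)
    if (!length(idx)) next
    mu_g <- base_mean * fold[, cl]
    mu_g[HORMONE_GENES] <- hormone_regime_means(
      hormone_regimes[[cl]], hormone_low_mean, hormone_high_mean, hormone_off_mean)
    mu <- outer(mu_g, lib[idx])
    counts[, idx] <- rnb(length(mu), mu, dispersion)
  }

  ann <- cell_annotation(
    cell_id = cell_ids,
    sample_id = sample_of_cell,
    group = sample_groups[match(sample_of_cell, sample_ids)],
    cluster = cluster_of_cell)

  de_truth <- lapply(names(clusters), function(cl) {
    data.frame(gene = de_genes[[cl]], log2_effect = rep(de_effect, length(de_genes[[cl]])),
               stringsAsFactors = FALSE)
  })
  names(de_truth) <- names(clusters)
  if (n_aggr) {
    de_truth[[AGGRESSIVE_CLUSTER]] <- data.frame(
      gene = prolif_genes, log2_effect = rep(prolif_effect, n_prolif),
      stringsAsFactors = FALSE)
  }

  truth <- structure(list(
    cluster_of_cell = cluster_of_cell,
    sample_of_cell = sample_of_cell,
    aggressive_cells = cell_ids[cluster_of_cell == AGGRESSIVE_CLUSTER],
    de_genes = de_truth,
    hormone_genes = HORMONE_GENES,
    hormone_regimes = hormone_regimes,
    mito_genes = mito_genes,
    prolif_genes = prolif_genes,
    mixing_weights = NULL,
    bulk_labels = NULL,
    seed = as.integer(seed),
    params = list(n_genes = n_genes, n_cells = n_cells, clusters = clusters,
                  de_fraction = de_fraction, de_effect = de_effect,
                  dispersion = dispersion, libsize_sigma = libsize_sigma,
                  aggressive_fraction = aggressive_fraction)
  ), class = "SyntheticTruth")

  list(counts = count_matrix(counts, gene_ids, cell_ids),
       annotation = ann, truth = truth)
}

centroid_matrix <- function(centroids) {
  if (is.matrix(centroids)) return(centroids)
  stopifnot(is.list(centroids), length(centroids) >= 1)
  genes <- names(centroids[[1]]$mean_expression)
  m <- vapply(centroids, function(cp) cp$mean_expression[genes], numeric(length(genes)))
  rownames(m) <- genes
  colnames(m) <- vapply(centroids, function(cp) cp$cluster, character(1))
  m
}

#' Generate a bulk cohort as noisy mixtures of cluster centroids
#'
#' Each bulk sample is a convex mixture of per-cluster mean expression
#' profiles (log-normalized space), with carcinoma-like samples receiving an
#' elevated weight on the aggressive cluster, multiplied by gene-wise
#' log-normal noise, restricted to a platform-dependent gene subset, and
#' masked with missing values — emulating the kind of 13-sample
#' microarray cohort (3 carcinomas, 5 invasive, 5 non-invasive adenomas)
#' that the single-cell classifier is transferred to.
#'
#' @param truth A `SyntheticTruth` from [generate_sc_dataset()].
#' @param centroids Per-cluster centroids: output of [compute_centroids()]
#'   (or a genes x clusters matrix) covering all truth clusters including
#'   `"T00"`.
#' @param n_samples Number of bulk samples (default 13).
#' @param carcinoma_aggressive_weight Mixture weight on the aggressive
#'   cluster in carcinoma-like samples.
#' @param base_aggressive_weight Aggressive weight in all other samples.
#' @param invasive_aggressive_weight Aggressive weight in invasive-like
#'   samples (defaults to `base_aggressive_weight`).
#' @param n_carcinoma,n_invasive Label layout (remaining samples are
#'   non-invasive-like).
#' @param noise_sigma Standard deviation of gene-wise log-normal noise.
#' @param na_rate Fraction of entries masked missing (must be < 1).
#' @param bulk_gene_fraction Fraction of centroid genes the bulk platform
#'   detects (the rest are absent from the cohort).
#' @param seed Integer seed.
#' @return A [bulk_cohort()] with per-sample `labels`
#'   (`carcinoma_like` / `invasive_like` / `noninvasive_like`) and the
#'   mixture weight matrix in field `mixing_weights`.
#' @export
generate_bulk_cohort <- function(truth, centroids, n_samples = 13,
                                 carcinoma_aggressive_weight = 0.4,
                                 base_aggressive_weight = 0.05,
                                 invasive_aggressive_weight = base_aggressive_weight,
                                 n_carcinoma = 3, n_invasive = 5,
                                 noise_sigma = 0.2, na_rate = 0.05,
                                 bulk_gene_fraction = 0.8,
                                 seed = 1L) {
  if (na_rate >= 1) ps_stop("na_rate = 1 leaves nothing to classify")
  stopifnot(na_rate >= 0, n_samples >= n_carcinoma + n_invasive)
  cm <- centroid_matrix(centroids)
  needed <- unique(truth$cluster_of_cell)
  missing_k <- setdiff(needed, colnames(cm))
  if (length(missing_k)) {
    ps_stop("centroids missing for cluster(s): ", paste(missing_k, collapse = ", "))
  }
  if (!(AGGRESSIVE_CLUSTER %in% colnames(cm))) {
    ps_stop("centroids must include the aggressive cluster '", AGGRESSIVE_CLUSTER, "'")
  }
  set.seed(as.integer(seed))

  labels <- c(rep("carcinoma_like", n_carcinoma),
              rep("invasive_like", n_invasive),
              rep("noninvasive_like", n_samples - n_carcinoma - n_invasive))
  w_aggr <- ifelse(labels == "carcinoma_like", carcinoma_aggressive_weight,
            ifelse(labels == "invasive_like", invasive_aggressive_weight,
                   base_aggressive_weight))

  others <- setdiff(colnames(cm), AGGRESSIVE_CLUSTER)
  weights <- matrix(0, n_samples, ncol(cm),
                    dimnames = list(sprintf("B%02d", seq_len(n_samples)), colnames(cm)))
  for (s in seq_len(n_samples)) {
    g <- stats::rgamma(length(others), shape = 1)
    weights[s, others] <- (1 - w_aggr[s]) * g / sum(g)
    weights[s, AGGRESSIVE_CLUSTER] <- w_aggr[s]
  }

  keep_n <- max(1L, round(bulk_gene_fraction * nrow(cm)))
  keep <- sort(sample(nrow(cm), keep_n))
  expr <- weights %*% t(cm[keep, , drop = FALSE])
  noise <- matrix(rlnorm(length(expr), 0, noise_sigma), nrow(expr), ncol(expr))
  expr <- expr * noise

  if (na_rate > 0) {
    mask <- matrix(runif(length(expr)) < na_rate, nrow(expr), ncol(expr))
    # never blank out an entire gene column
    full <- colSums(!mask) == 0
    mask[1, full] <- FALSE
    expr[mask] <- NA_real_
  }

  out <- bulk_cohort(expr, rownames(weights), rownames(cm)[keep], labels = labels)
  out$mixing_weights <- weights
  out
}

#' Generate a perturbed "foreign species" reference atlas
#'
#' Builds an atlas sharing a fraction of the gene universe, with gene-wise
#' log-normal scale distortions and cells placed around each cluster
#' centroid in log-normalized space — the situation met when mapping human
#' pituitary cells onto a mouse or rat reference restricted to common genes.
#' With `scale_sigma = 0`, `gene_keep_fraction = 1` and `cell_noise_sd = 0`
#' every atlas cell equals its source centroid exactly.
#'
#' @param centroids Output of [compute_centroids()] or a genes x clusters
#'   matrix of mean log-normalized expression.
#' @param gene_keep_fraction Fraction of genes the atlas shares.
#' @param scale_sigma Standard deviation of the gene-wise log-normal scale
#'   distortion.
#' @param cells_per_cluster Atlas cells drawn per cluster.
#' @param cell_noise_sd Standard deviation of per-cell Gaussian noise around
#'   the (distorted) centroid, truncated at zero.
#' @param seed Integer seed.
#' @return A list with `expression` (a [normalized_matrix()] of atlas cells)
#'   and `annotation` ([cell_annotation()] holding each cell's generating
#'   cluster).
#' @export
generate_reference_atlas <- function(centroids, gene_keep_fraction = 0.8,
                                     scale_sigma = 0.3, cells_per_cluster = 20,
                                     cell_noise_sd = 0.1, seed = 1L) {
  stopifnot(gene_keep_fraction > 0, gene_keep_fraction <= 1, cells_per_cluster >= 1)
  cm <- centroid_matrix(centroids)
  keep_n <- round(gene_keep_fraction * nrow(cm))
  if (keep_n < 50) {
    ps_stop("gene_keep_fraction leaves ", keep_n, " shared genes (< 50)")
  }
  set.seed(as.integer(seed))
  keep <- sort(sample(nrow(cm), keep_n))
  cm <- cm[keep, , drop = FALSE]
  scale_g <- rlnorm(nrow(cm), 0, scale_sigma)

  k <- ncol(cm)
  n_cells <- k * cells_per_cluster
  vals <- matrix(0, nrow(cm), n_cells)
  cluster_of <- character(n_cells)
  for (i in seq_len(k)) {
    idx <- (i - 1) * cells_per_cluster + seq_len(cells_per_cluster)
    base <- cm[, i] * scale_g
    noise <- if (cell_noise_sd > 0) {
      matrix(rnorm(nrow(cm) * cells_per_cluster, 0, cell_noise_sd), nrow(cm))
    } else 0
    vals[, idx] <- pmax(base + noise, 0)
    cluster_of[idx] <- colnames(cm)[i]
  }
  cell_ids <- sprintf("ref%05d", seq_len(n_cells))
  nm <- normalized_matrix(vals, rownames(cm), cell_ids)
  ann <- cell_annotation(cell_ids, rep("atlas", n_cells),
                         rep("normal", n_cells), cluster_of)
  list(expression = nm, annotation = ann)
}
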