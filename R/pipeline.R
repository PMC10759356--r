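# End-to-end orchestration on generated data: one config, one global seed,
# per-stage derived seeds, TSV/JSON outputs and a JSON manifest.

pipeline_schema <- list(
  seed = NULL, out_dir = NULL, quiet = NULL,
  simulate = c("n_genes", "n_cells", "clusters", "de_fraction", "de_effect",
               "dispersion", "libsize_sigma", "mito_fraction",
               "aggressive_fraction", "proliferation_set_size", "prolif_effect",
               "n_samples"),
  qc = c("umi_min", "umi_max", "genes_min", "genes_max", "mito_max",
         "dissoc_max", "min_cells_per_gene"),
  normalize = c("scale_factor"),
  markers = c("min_pct", "prefilter_lfc", "adjust", "min_log_fc", "max_adj_p"),
  signatures = c("n_bins", "n_ctrl"),
  pseudobulk = c("n_pcs"),
  classify = c("n_trees", "n_pos", "n_neg", "k_impute", "min_log_fc",
               "max_adj_p", "n_bulk_samples", "carcinoma_aggressive_weight",
               "base_aggressive_weight", "noise_sigma", "na_rate",
               "bulk_gene_fraction")
)

validate_config <- function(cfg) {
  unknown_top <- setdiff(names(cfg), names(pipeline_schema))
  if (length(unknown_top)) {
    ps_stop("unknown config key(s): ", paste(unknown_top, collapse = ", "))
  }
  for (sect in names(pipeline_schema)) {
    allowed <- pipeline_schema[[sect]]
    if (is.null(allowed) || is.null(cfg[[sect]])) next
    unknown <- setdiff(names(cfg[[sect]]), allowed)
    if (length(unknown)) {
      ps_stop("unknown config key(s) in '", sect, "': ",
              paste(unknown, collapse = ", "))
    }
  }
  if (is.null(cfg$seed)) ps_stop("config must set 'seed'")
  if (is.null(cfg$out_dir)) ps_stop("config must set 'out_dir'")
  invisible(cfg)
}

get_cfg <- function(cfg, sect, key, default) cfg[[sect]][[key]] %||% default

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline on generated data
#'
#' Executes simulate -> qc -> normalize -> markers -> signatures /
#' pseudo-bulk -> classify in dependency order, writing TSV/JSON artifacts
#' and a manifest into `out_dir`. All stage seeds derive deterministically
#' from the global seed, so re-running the same config reproduces
#' byte-identical outputs.
#'
#' @param config A named list, or path to a YAML file with the same
#'   structure. Must set `seed` and `out_dir`; optional sections
#'   `simulate`, `qc`, `normalize`, `markers`, `signatures`, `pseudobulk`,
#'   `classify` override stage defaults. Unknown keys are rejected.
#' @return Invisibly, the manifest (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  if (isTRUE(cfg$quiet)) {
    old <- options(pitscape.quiet = TRUE)
    on.exit(options(old), add = TRUE)
  }
  out_dir <- cfg$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  artifacts <- list()

  # --- simulate --------------------------------------------------------
  clusters <- unlist(get_cfg(cfg, "simulate", "clusters",
                             list(T01 = 0.3, T02 = 0.3, T03 = 0.4)))
  sim <- generate_sc_dataset(
    n_genes = get_cfg(cfg, "simulate", "n_genes", 1000),
    n_cells = get_cfg(cfg, "simulate", "n_cells", 1200),
    clusters = clusters,
    de_fraction = get_cfg(cfg, "simulate", "de_fraction", 0.05),
    de_effect = get_cfg(cfg, "simulate", "de_effect", 2),
    dispersion = get_cfg(cfg, "simulate", "dispersion", 0.1),
    libsize_sigma = get_cfg(cfg, "simulate", "libsize_sigma", 0.3),
    mito_fraction = get_cfg(cfg, "simulate", "mito_fraction", 0.05),
    aggressive_fraction = get_cfg(cfg, "simulate", "aggressive_fraction", 0.03),
    proliferation_set_size = get_cfg(cfg, "simulate", "proliferation_set_size", 40),
    prolif_effect = get_cfg(cfg, "simulate", "prolif_effect", 2),
    n_samples = get_cfg(cfg, "simulate", "n_samples", 4),
    seed = derive_seed(seed, "simulate"))
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(list(
    cluster_of_cell = as.list(sim$truth$cluster_of_cell),
    aggressive_cells = sim$truth$aggressive_cells,
    seed = sim$truth$seed), truth_path, auto_unbox = TRUE)
  artifacts$truth <- truth_path

  # --- qc + normalize ---------------------------------------------------
  thresholds <- qc_thresholds(
    umi_min = get_cfg(cfg, "qc", "umi_min", 0),
    umi_max = get_cfg(cfg, "qc", "umi_max", Inf),
    genes_min = get_cfg(cfg, "qc", "genes_min", 0),
    genes_max = get_cfg(cfg, "qc", "genes_max", Inf),
    mito_max = get_cfg(cfg, "qc", "mito_max", 0.5),
    dissoc_max = get_cfg(cfg, "qc", "dissoc_max", 1),
    min_cells_per_gene = get_cfg(cfg, "qc", "min_cells_per_gene", 3))
  qc <- apply_qc(sim$counts, list(mito = sim$truth$mito_genes), thresholds)
  qc_path <- file.path(out_dir, "qc_report.json")
  jsonlite::write_json(qc$report, qc_path, auto_unbox = TRUE)
  artifacts$qc_report <- qc_path
  nm <- lognormalize(qc$counts,
                     scale_factor = get_cfg(cfg, "normalize", "scale_factor", 10000))
  ann <- sim$annotation[sim$annotation$cell_id %in% nm$cell_ids, ]
  clusters_of <- stats::setNames(ann$cluster, ann$cell_id)
  samples_of <- stats::setNames(ann$sample_id, ann$cell_id)

  # --- markers ----------------------------------------------------------
  markers <- find_markers(
    nm, clusters_of,
    min_pct = get_cfg(cfg, "markers", "min_pct", 0.1),
    prefilter_lfc = get_cfg(cfg, "markers", "prefilter_lfc", 0.1),
    adjust = get_cfg(cfg, "markers", "adjust", "BH"))
  artifacts$markers <- write_tsv(markers, file.path(out_dir, "markers.tsv"))
  filtered <- filter_markers(
    markers,
    min_log_fc = get_cfg(cfg, "markers", "min_log_fc", 0.25),
    max_adj_p = get_cfg(cfg, "markers", "max_adj_p", 0.01))
  artifacts$filtered_markers <-
    write_tsv(filtered, file.path(out_dir, "filtered_markers.tsv"))

  # --- signatures -------------------------------------------------------
  prolif <- gene_set("proliferation", sim$truth$prolif_genes)
  sig <- module_score(
    nm, prolif,
    n_bins = get_cfg(cfg, "signatures", "n_bins", 24),
    n_ctrl = get_cfg(cfg, "signatures", "n_ctrl", 100),
    seed = derive_seed(seed, "signatures"))
  artifacts$proliferation_score <-
    write_tsv(sig, file.path(out_dir, "proliferation_score.tsv"))

  # --- pseudobulk -------------------------------------------------------
  pb <- build_pseudobulk(nm, samples_of)
  n_pcs <- min(get_cfg(cfg, "pseudobulk", "n_pcs", 20), length(pb) - 1)
  coords <- pc_embed(pb, n_pcs = n_pcs)
  simmat <- cosine_similarity_matrix(coords)
  artifacts$pseudobulk_similarity <- write_tsv(
    data.frame(sample_id = simmat$ids, simmat$values, check.names = FALSE),
    file.path(out_dir, "pseudobulk_similarity.tsv"))

  # --- classify ---------------------------------------------------------
  centroids <- compute_centroids(nm, clusters_of)
  bulk <- generate_bulk_cohort(
    sim$truth, centroids,
    n_samples = get_cfg(cfg, "classify", "n_bulk_samples", 13),
    carcinoma_aggressive_weight =
      get_cfg(cfg, "classify", "carcinoma_aggressive_weight", 0.4),
    base_aggressive_weight =
      get_cfg(cfg, "classify", "base_aggressive_weight", 0.05),
    noise_sigma = get_cfg(cfg, "classify", "noise_sigma", 0.2),
    na_rate = get_cfg(cfg, "classify", "na_rate", 0.05),
    bulk_gene_fraction = get_cfg(cfg, "classify", "bulk_gene_fraction", 0.8),
    seed = derive_seed(seed, "bulk"))
  genes <- select_classifier_genes(
    markers, bulk$gene_ids,
    min_log_fc = get_cfg(cfg, "classify", "min_log_fc", 0.75),
    max_adj_p = get_cfg(cfg, "classify", "max_adj_p", 0.05))
  sel_path <- file.path(out_dir, "selection_log.json")
  jsonlite::write_json(genes$selection_log, sel_path, auto_unbox = TRUE)
  artifacts$selection_log <- sel_path
  sc_feat <- harmonize_sc(nm, genes)
  bulk_feat <- harmonize_bulk(bulk, genes,
                              k_impute = get_cfg(cfg, "classify", "k_impute", 10))
  labels <- ifelse(rownames(sc_feat) %in% sim$truth$aggressive_cells,
                   "aggressive", "non_aggressive")
  model <- train_classifier(
    sc_feat, labels,
    n_trees = get_cfg(cfg, "classify", "n_trees", 500),
    n_pos = get_cfg(cfg, "classify", "n_pos", 1500),
    n_neg = get_cfg(cfg, "classify", "n_neg", 500),
    seed = derive_seed(seed, "classify"))
  preds <- predict_aggressiveness(model, bulk_feat)
  preds$label <- bulk$labels[match(preds$sample_id, bulk$sample_ids)]
  artifacts$predictions <- write_tsv(preds, file.path(out_dir, "predictions.tsv"))

  # --- manifest ---------------------------------------------------------
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pitscape")),
    seed = seed,
    stage_seeds = list(simulate = derive_seed(seed, "simulate"),
                       signatures = derive_seed(seed, "signatures"),
                       bulk = derive_seed(seed, "bulk"),
                       classify = derive_seed(seed, "classify")),
    config = cfg_path,
    artifacts = artifacts)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  ps_log("pipeline complete: ", length(artifacts), " artifacts in ", out_dir)
  invisible(manifest)
}
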