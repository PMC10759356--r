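# pitscape

Single-cell transcriptomic analysis of pituitary neuroendocrine tumors
(PitNETs), and transfer of single-cell derived aggressiveness signatures to
bulk tumor cohorts.

PitNETs arise from the hormone-producing lineages of the anterior pituitary
(PIT1, TPIT, SF1). Single-cell RNA-seq of these tumors reveals, among other
things, a small cross-sample subpopulation of "aggressive" tumor cells with
an elevated proliferation program (*PTTG1*, *TOP2A*-like markers). The
clinically interesting question is whether the expression signature of that
subpopulation, learned at single-cell resolution, can grade *bulk* tumor
samples — for which far more cohorts with clinical annotation exist — by
their probability of being aggressive (carcinoma-like vs invasive vs
non-invasive adenoma).

`pitscape` implements that analysis as a tested, reusable pipeline for
anyone working with clustered scRNA-seq count data plus an external bulk
cohort:

* **QC and normalization** — the four per-cell filters (UMI range, detected
  genes, mitochondrial fraction, dissociation fraction), the ≥3-cells gene
  filter, and TPM-like log normalization
  `value = log(count / total × 10⁴ + 1)`.
* **Highly variable genes and scaling** — variance standardized against a
  fitted mean–variance trend (vst-style) and per-gene OLS regression of
  covariates (total UMIs, mitochondrial fraction) followed by unit-variance
  scaling.
* **Cluster markers** — one-vs-rest Wilcoxon rank-sum tests (exact by
  dynamic programming for small groups, tie-corrected normal approximation
  otherwise), log₂ fold changes of de-logged means, Benjamini–Hochberg
  adjustment, and the two filter regimes (logFC > 0.25 & adjP < 0.01 for
  cluster markers; logFC > 0.75 & adjP < 0.05 for classifier features).
* **Signatures** — mean-expression signatures, binned-control module scores
  (AddModuleScore-style), cell-cycle phase calls, ternary
  epithelial/mesenchymal/stemness state scores, and the hormone
  co-expression quadrant analysis (e.g. *GH1* vs *PRL* low/high fractions).
* **Reference mapping** — scmap-style assignment of query cells to the
  cluster centroid with maximal Pearson correlation, after restriction to a
  shared (orthology-mapped) gene space.
* **Pseudo-bulk** — per-sample sums of log-normalized expression, 20-PC
  embedding, pairwise cosine similarity; plus a transcription-factor
  dendrogram between clusters (Euclidean distances between cluster means in
  PC space, hierarchical clustering, Newick export).
* **Aggressiveness classifier** — the marker→filter→bulk-detected gene
  selection chain, KNN imputation + quantile normalization + z-scoring of
  the bulk cohort, per-gene z-scoring of the cells, a class-balanced random
  forest (4000 trees, stratified 1500/500 sampling by default) trained on
  cells, and per-sample aggressiveness probabilities with ranks.
* **Synthetic data with ground truth** — a negative-binomial generator for
  clustered counts with hormone-gene programs, a planted cross-sample
  aggressive subpopulation, mitochondrial blocks and variable library
  sizes; bulk cohorts as noisy centroid mixtures with missing values; and
  perturbed reference atlases. Every statistical claim in the test suite is
  checked against this generator's recorded truth.

## Worked example

Generate a cohort with a planted 3% aggressive subpopulation, find its
markers, and grade a 13-sample bulk cohort (3 carcinoma-like samples mixed
with elevated aggressive-cluster weight):

```r
library(pitscape)

sim <- generate_sc_dataset(n_genes = 800, n_cells = 1000,
                           clusters = c(T01 = 0.5, T02 = 0.5),
                           aggressive_fraction = 0.03, seed = 1)
nm <- lognormalize(sim$counts)
cl <- setNames(sim$annotation$cluster, sim$annotation$cell_id)

mk <- find_markers(nm, cl, only_clusters = "T00")
head(filter_markers(mk[order(mk$adj_p), ], 0.25, 0.01), 3)
#>   cluster       gene log_fc  p_value    adj_p pct_in pct_out
#> 1     T00 PROLIF-012   2.17 2.08e-20 1.98e-18      1   0.951
#> 2     T00 PROLIF-016   2.23 1.08e-20 1.98e-18      1   0.996
#> 3     T00 PROLIF-037   1.95 1.97e-20 1.98e-18      1   0.995
```

The planted proliferation genes dominate the aggressive cluster's marker
table, each roughly at the planted 4-fold (log₂ ≈ 2) effect. Transferring
to bulk:

```r
cent  <- compute_centroids(nm, cl)
bulk  <- generate_bulk_cohort(sim$truth, cent, seed = 2)
genes <- select_classifier_genes(mk, bulk$gene_ids)
#> classifier genes: 555 tested -> 51 passing filter -> 45 detected in bulk

model <- train_classifier(harmonize_sc(nm, genes),
                          ifelse(nm$cell_ids %in% sim$truth$aggressive_cells,
                                 "aggressive", "non_aggressive"),
                          n_trees = 500, seed = 3)
pred <- predict_aggressiveness(model, harmonize_bulk(bulk, genes))
pred$label <- bulk$labels
head(pred[order(pred$rank), ], 5)
#>    sample_id p_aggressive p_non_aggressive rank            label
#> 2        B02        0.328            0.672    1   carcinoma_like
#> 1        B01        0.142            0.858    2   carcinoma_like
#> 3        B03        0.130            0.870    3   carcinoma_like
#> 13       B13        0.114            0.886    4 noninvasive_like
#> 11       B11        0.076            0.924    5 noninvasive_like
```

The three carcinoma-like samples take the top three aggressiveness ranks.
`p_aggressive` is the fraction of forest trees voting "aggressive"; with a
small planted subpopulation the absolute probabilities are modest — the
clinically relevant output is the ranking.

A full run of every stage, driven by one YAML config and a single seed, is

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "pitscape"))
```

which writes marker tables, signature scores, pseudo-bulk similarities,
predictions and a JSON manifest into the configured output directory.

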