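---
title: "Methods: models, parameters and design choices in pitscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in pitscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pitscape` packages the computational core of a PitNET single-cell study —
marker discovery, gene-set scoring, atlas mapping, pseudo-bulk comparison,
and a single-cell→bulk aggressiveness classifier — around a synthetic-data
generator with recorded ground truth. This vignette is the package's own
account of the underlying models, the parameters that matter, and the
choices made where the design was genuinely open.

## Normalization model

Counts are normalized per cell to a fixed pseudo-depth and log-transformed:

$$v_{gc} = \log\!\left(\frac{x_{gc}}{\sum_g x_{gc}} \cdot s + 1\right),$$

with scale factor $s = 10{,}000$ by default and the **natural** logarithm.
The log base is a genuine degree of freedom in this kind of pipeline; we
follow the dominant single-cell convention (natural log) and record the
base in the `NormalizedMatrix` object so downstream consumers never have to
guess. Fold changes, in contrast, are reported in **log₂** units (the unit
in which the 0.25 and 0.75 marker thresholds are interpreted), computed on
de-logged means with a pseudo-count of 1:
$\mathrm{lfc}_g = \log_2(\bar e_{g,\text{in}} + 1) - \log_2(\bar
e_{g,\text{out}} + 1)$ where $\bar e = \text{mean}(\exp(v) - 1)$.

Quality control applies four per-cell filters (UMI range, detected-gene
range, mitochondrial fraction, dissociation-gene fraction), cells first,
then removes genes detected in fewer than 3 cells. No universal numeric
cutoffs exist for the cell filters, so they are configuration with
documented defaults (UMIs 500–60,000, genes 200–8,000, mitochondrial
fraction ≤ 0.2, dissociation fraction ≤ 0.05); the reference-atlas
convention (≥ 200 genes, ≤ 50% mitochondrial) is one constructor call away.
QC is idempotent in practice but not by construction: removing
low-prevalence genes lowers cell totals, so a second pass could in
principle remove further cells. The test suite checks idempotency under
typical thresholds rather than asserting it universally.

## Highly variable genes

Genes are scored by variance standardized against a smooth mean–variance
trend fitted on raw counts: a local polynomial regression (loess, span 0.3,
degree 2) of $\log_{10}(\mathrm{var})$ on $\log_{10}(\mathrm{mean})$
predicts each gene's expected standard deviation; per-cell standardized
counts are clipped at $\pm\sqrt{n_\text{cells}}$ and the variance of the
clipped values is the score. The span is the one tunable with real
influence: smaller spans chase the planted structure into the trend itself.
Ties are broken by gene id so selection is deterministic. The trend is
unfittable below 10 genes, which is an error rather than a silent fallback.

## Marker detection

Markers are one-vs-rest two-sided Wilcoxon rank-sum tests. For
$n \cdot m \le 200$ (product of group sizes) the permutation distribution
of the rank sum is enumerated **exactly** by dynamic programming over
doubled midranks — exact under any tie pattern, unlike the classical
no-ties recursion — and the p-value is the tail mass at least as extreme as
observed. Larger problems use the normal approximation with tie-corrected
variance and a 0.5 continuity correction. The test suite holds the exact
path against an independent brute-force enumeration oracle over all
$\binom{N}{n}$ assignments (1000 random tied instances, group sizes ≤ 8)
and the approximate path against null calibration at $\alpha \in \{0.01,
0.05\}$ within 3 binomial standard errors.

Multiple testing uses Benjamini–Hochberg by default. Marker pipelines in
this field differ here (Bonferroni is a common default); the adjustment is
an explicit enum (`BH`, `bonferroni`) so either convention is reproducible,
and adjusted p-values are computed over the full tested set. The detection
prefilter (expressed in ≥ 10% of either group, |lfc| ≥ 0.1) mirrors common
practice and is switched off (`min_pct = 0, prefilter_lfc = 0`) whenever a
test needs the complete null distribution.

Filtering is strict (`log_fc > t`, `adj_p < q`): a row at exactly the
threshold is excluded. Two regimes are used: 0.25 / 0.01 for cluster
markers and 0.75 / 0.05 for classifier features.

## Signatures, cell cycle, ternary and quadrant analyses

Mean-expression signatures are plain per-cell means over set genes. Module
scores subtract an expression-matched control: all genes are binned into 24
equal-frequency bins by mean expression (ties broken by gene id), 100
control genes per set gene are drawn with replacement from the gene's bin,
and the score is mean(set) − mean(pooled controls). A bin containing only
set genes falls through to the nearest non-degenerate bin with a log line.
Control draws are seeded, so scores are exactly reproducible. Calibration
is checked on random sets drawn from the *unplanted* background of the
generator: sets that happen to include planted programs (the hormone pair,
DE blocks) are legitimately non-null and are not a calibration standard.

Cell-cycle phase is G1 when both S and G2/M module scores are ≤ 0,
otherwise the arg-max phase (ties going to S). Ternary state scores divide
three non-negative mean-expression signatures by their sum — module scores
are rejected by a non-negativity precondition since simplex coordinates
from signed scores would be meaningless — and all-zero cells are placed at
the barycenter (1/3, 1/3, 1/3) with a logged count.

The quadrant analysis calls a gene "expressed" above `expr_min` (default 0,
i.e. any detection) and "high" at or above `high_min`. No published numeric
high/low hormone cutoff exists, so the default `high_min` is scale-free:
the per-gene upper-quartile value over expressing cells; any fixed value
can be supplied instead. Categories (`neither`, `A_only`, `B_only`,
`both_low`, `both_high`, `both_mixed`) are exhaustive and exclusive, and
per-group proportions sum to one exactly.

## Reference mapping

Query and reference are restricted to a shared gene space (case-normalized
symbol identity, or an explicit one-to-one ortholog table; fewer than 50
shared genes is an error). Each reference cluster is its centroid (mean
log-normalized expression); each query cell is assigned to the centroid
with maximal Pearson correlation over all shared genes. Correlation on the
full shared space, rather than an HVG subset, is the default because
per-cell correlation mapping is most stable with many genes; a subset
argument exists for atlas QC. Zero-variance cells or centroids get r = 0
for affected pairs (logged), ties break by label order, and `min_r` can
mark weak assignments `"unassigned"` (no threshold by default — similarity
reporting, not hard gating, is the primary use).

## Pseudo-bulk and dendrograms

A sample's pseudo-bulk is the plain gene-wise **sum** of log-normalized
expression over its cells — deliberately not re-normalized, matching the
way such profiles are usually built; profiles are then centered/scaled per
gene (constant genes dropped with a log line) and embedded by SVD. Axis
signs are fixed deterministically (largest-magnitude loading positive) so
embeddings are exactly reproducible; at full rank the embedding is an
isometry of the scaled gene space, which the tests assert at 1e-8. Sample
similarity is cosine similarity of the top-20 (or fewer) PC coordinates.
The transcription-factor dendrogram takes cluster means in PC space of the
TF-restricted scaled matrix, Euclidean distances, and complete linkage by
default — the default of the standard hierarchical-clustering routine;
average and Ward linkage are exposed because nothing in the procedure pins
the choice. Trees export as Newick text.

## The aggressiveness classifier

The transfer pipeline follows four steps.

1. **Gene selection.** The aggressive cluster's marker rows are filtered at
   log₂FC > 0.75 and adjusted p < 0.05 (positive only), then intersected
   with the genes the bulk platform detects. Every stage count is recorded
   in a selection log, so the provenance of the final feature set is
   auditable.
2. **Bulk harmonization.** Missing entries are imputed gene-wise by KNN:
   the k = 10 genes nearest in Euclidean distance over co-observed samples,
   averaged at the missing sample (neighbors unobserved there are skipped;
   the gene mean is the last resort). Quantile normalization then forces
   all samples onto one distribution (tied ranks receive the mean of the
   tied reference quantiles), and each gene is z-scored with the n−1
   denominator. Imputation and normalization run on the **full** cohort
   before the feature genes are extracted: on the selected genes alone,
   a genuinely aggressive sample — elevated on *all* features at once —
   would be flattened by quantile normalization, which removes exactly
   such common shifts.
3. **Single-cell harmonization.** The log-normalized matrix restricted to
   the selected genes is z-scored per gene over cells.
4. **Ensemble.** A random forest (4000 trees by default) is trained on the
   cell z-scores with stratified per-tree sampling — 1500 aggressive vs
   500 non-aggressive draws with replacement — so the rare aggressive class
   is not swamped. When a class has fewer cells than its per-tree quota the
   quota is capped at the class frequency (with a log line); the published
   defaults assume ~2000 aggressive cells, while scaled-down synthetic runs
   may have a few dozen. Bulk samples are scored by the fraction of trees
   voting aggressive and ranked by decreasing probability (ties by sample
   id). Feature columns must match the training order exactly; mismatches
   are an error, never a silent reorder.

With a small planted subpopulation the absolute tree-vote probabilities
are modest; the ranking is the meaningful output, and the test suite
asserts exactly that (carcinoma-like samples in the top ranks, AUC across
seeded cohorts).

## The synthetic-data generator

The generator is first-class, tested code, and its defaults define the
conditions under which the pipeline's statistical guarantees are stated.

* **Counts**: negative binomial with gene-wise log-normal baseline means
  (meanlog 0, sdlog 1), cluster-specific fold shifts of $2^{\text{de\_effect}}$
  on planted DE blocks, per-cell log-normal library factors
  (sigma 0.3), and dispersion 0.1 (variance $\mu + 0.1\mu^2$) — typical
  magnitudes for droplet scRNA-seq at shallow depth. Dispersion 0 falls
  back to Poisson.
* **Composition** is deterministic (largest-remainder apportionment of
  cluster proportions), so planted fractions are exact and recovery tests
  measure classification error, not multinomial sampling noise.
* **Aggressive cells** (default 2–3%) form cluster `"T00"`, spread
  round-robin across every sample, with a disjoint proliferation program
  (default 50 genes at moderately high baseline, shifted 4-fold) — the
  structure of a rare cross-sample proliferative subpopulation.
* **Hormone pair** `HORM-A`/`HORM-B` follows one of five per-cluster
  regimes (both-low, both-high, A-only, B-only, neither) with mean counts
  20 / 400 / 0.05 for low / high / off — separated enough in log space
  that quadrant categories are recoverable, close enough that the cutoff
  matters. Because the regimes are *planted structure*, null-calibration
  experiments either match regimes across clusters or exclude the pair
  from random draws; with unequal regimes the pair shifts library sizes
  and thereby every normalized gene, which is a real compositional effect,
  not a bug.
* **Bulk cohorts** are convex mixtures of cluster centroids in
  log-normalized space (carcinoma-like samples at aggressive weight 0.4 vs
  0.05 elsewhere, remaining weight Dirichlet-distributed), multiplied by
  gene-wise log-normal noise (sigma 0.2), restricted to a platform subset
  (80% of genes) and masked at a 5% missing rate — mirroring a 13-sample
  microarray cohort with 3 carcinomas and 5 invasive adenomas.
* **Reference atlases** share a fraction of the gene universe, distort
  genes by log-normal scale factors, and place cells around each centroid.
  The atlas returns expression directly in log-normalized space — not
  counts — so that the noiseless configuration (`scale_sigma = 0`,
  `cell_noise_sd = 0`, full gene overlap) reproduces centroids *exactly*
  and mapping accuracy is provably 100% there; integer counts could not
  represent that limit.

What the generator does **not** emulate: gene–gene correlation beyond
cluster/program structure, doublets, ambient RNA, batch effects, or
realistic gene-length/GC biases. Passing tests therefore demonstrate
correctness of the statistical machinery under a well-specified model, not
robustness to every artifact of real data.

## Numerical conventions and degenerate inputs

* Standard deviations use the n−1 denominator everywhere.
* Constant genes: z-scored to zero columns (logged), dropped before PCA
  (logged), scaled to zero rows after regression (logged) — never errors.
* Zero-variance cells or centroids: correlation defined as 0, logged.
* Zero-total cells are an error at normalization, naming the cell.
* All tie-breaks are deterministic (gene id, label order, sample id), so
  every result is exactly reproducible under a fixed seed; one global seed
  derives per-stage seeds by stage-name hashing, keeping each stage
  independently re-runnable.
* Gene-wise KNN imputation is exact only when a masked gene has ≥ k
  neighbors with *identical* profiles observed at the missing sample; the
  imputation tests use replicated-profile rank-1 fixtures that satisfy
  this, and real cohorts should expect interpolation error proportional to
  neighbor spacing.

## Problem sizes

The test and acceptance workloads use 800–2000 genes and 1000–5000 cells
per dataset, 13-sample bulk cohorts, 500-tree forests, and 20 seeded
repetitions of the transfer experiment — sizes at which every statistical
property under test (calibration within binomial error bands, ≥ 90%
recovery rates, AUC) is already stable, while a full run of the suite
stays in the low minutes on a single core.

## Known limitations

* Clustering itself (graph clustering, UMAP) is out of scope; cluster
  labels are inputs, from the generator's truth or the user.
* Batch correction is out of scope; the generator plants no batch effects.
* The ensemble's probability scale is not calibrated across modalities —
  rankings transfer, absolute probabilities need not.
* Ortholog handling is table-driven; no built-in cross-species gene maps
  are shipped.
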