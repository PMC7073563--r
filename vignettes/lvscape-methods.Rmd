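---
title: "Methods: latent-variable landscape analysis of NF1 nerve sheath tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent-variable landscape analysis of NF1 nerve sheath tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvscape)
```

## The problem

Neurofibromatosis type 1 (NF1) gives rise to several histologically distinct
nerve sheath tumor types — cutaneous neurofibromas (cNF), plexiform
neurofibromas (pNF), neurofibromas without further subtyping (NF), and
malignant peripheral nerve sheath tumors (MPNST). Bulk RNA-seq cohorts for
these rare tumors are small (tens of samples) and assembled from multiple
studies, so the feature space (~20k genes) dwarfs the sample count and batch
structure is confounded with biology. `lvscape` implements a transfer-learning
workflow for this regime: expression is projected into a latent-variable (LV)
space learned on a large independent compendium (a PLIER-style model), and the
LVs — a few hundred features with pathway-level interpretability — feed all
downstream characterization: supervised selection of tumor-type-defining LVs,
immune-microenvironment scoring, regulon (protein) activity, LV clustering
with drug-target enrichment, and gene-variant association.

Because the motivating cohorts are controlled-access, the package ships a
first-class synthetic-data module (`gen_model()`, `gen_cohort()`,
`gen_regulons()`, `gen_variants()`, `gen_drug_sets()`,
`gen_immune_mixture()`) that generates inputs with the statistical structure
the analysis assumes and records the ground truth of every planting, so the
whole pipeline is testable end to end without external data.

## Projection into latent-variable space

A PLIER-style model supplies a non-negative, sparse loading matrix $Z$
(genes $\times$ LVs) and a ridge constant $\lambda_2$. After per-gene
z-scoring (`zscore_genes()`; sample SD, zero-variance genes set to zero and
flagged), new samples $Y'$ are projected by the ridge solve

$$ B \;=\; (Z^\top Z + \lambda_2 I)^{-1} Z^\top Y' , $$

with $Y'$ restricted to the model's genes and genes absent from the input
imputed as 0 — the post-standardization mean, the least-informative choice.
`project_lv()` refuses to run below a configurable minimum gene overlap
(default 20%).

LVs with near-duplicate loadings carry redundant information; `dedup_lvs()`
drops one member of every pair of loading columns with Pearson correlation
above 0.5. The rule is a greedy ascending scan that keeps the earlier-indexed
LV — the deterministic tie-break is ours; any single-member elimination rule
satisfies the pairwise constraint, and reproducibility requires picking one.

`pca_batch_assessment()` quantifies how much study (batch) structure survives
projection: centered PCA is run separately in gene space and LV space
(samples as observations, first 2 PCs by default), all within-study pairwise
Euclidean distances are collected, each space's distances are divided by that
space's mean overall pairwise distance, and the two normalized distance sets
are compared with a two-sided Wilcoxon rank-sum test (normal approximation
with tie correction; the pair counts here are large). The normalization is
required because the two spaces have incommensurable scales; dividing by the
mean overall distance makes "how tight are study clusters relative to the
whole cloud" comparable across spaces. Note the direction semantics: a batch
effect *tightens* a space's normalized within-study distances (between-study
pairs inflate the overall mean), so the space with the smaller normalized
within-study distances is the one with *more* batch structure.

## Ensemble-of-forests feature selection

`split_model_test()` first holds out a stratified independent test set
(20% per tumor type, minimum one sample). On the model set,
`tune_hyperparams()` grid-searches `mtry` (1..100) and `ntrees`
(250/500/1000/2000) by stratified fivefold cross-validation on macro-F1,
with ties resolved to the smallest `ntrees`, then smallest `mtry`.

`run_ensemble()` then draws many (500 at full scale) stratified 75/25
train/holdout resamples without replacement, trains a random forest
(`randomForest`, the classical Breiman algorithm with explicit `mtry` and
`ntree`) on each, and records for every resample:

* per-class F1 (one-vs-rest from the multiclass confusion matrix; a class
  with no true and no predicted positives scores 0 by convention), on the
  resample's holdout part or on the fixed independent test set;
* per-class permutation importance (the forest's raw importance — mean
  decrease in class-wise accuracy when the feature is permuted);
* Gini importance (mean decrease in node impurity).

`select_top_features()` ranks features per class by median importance over
the resamples and takes the top 40 per class (ties broken by feature id);
the union of the four lists is the restricted feature set. The default
ranking metric is *per-class permutation importance*: Gini importance is
class-agnostic, so a per-class top-40 under Gini would produce four
identical lists, which cannot yield the class-specific signatures this
selection exists to find; the Gini ranking remains available as
`metric = "gini"` and is recorded alongside.

Retraining on the restricted set and evaluating on the independent test set
gives a second F1 distribution per class; `compare_restricted()` contrasts
the two with Mood's median test — pool the samples, count values above
versus at-or-below the pooled median, chi-square on the 2×2 table without
continuity correction; degenerate tables (e.g. both distributions identical)
return p = 1.

## Tumor microenvironment

`marker_scores()` is the marker-based abundance estimator (as in
MCP-counter): a cell type's score in a sample is the arithmetic mean of the
log2 expression of its marker genes. `deconvolve_fractions()` estimates
cell-type fractions against a signature matrix by non-negative least squares
per sample (`pracma::lsqnonneg` on linear-scale expression), normalized to
sum to one, with a per-sample residual RMSE. This is a deterministic,
dependency-light alternative to support-vector deconvolution; it recovers
exact mixtures to numerical precision and is adequate for the correlation
analyses it feeds, but it does not reproduce SVR-specific behavior on
collinear signatures. `correlate_immune_lv()` correlates every
(LV, cell type) pair (Pearson by default, Spearman switchable, optionally
within tumor types) with Benjamini–Hochberg q-values across all reported
pairs; constant vectors are reported as `NA` and excluded from the
adjustment.

## Regulon activity

`rank_signature()` converts each sample to a gene signature by mapping
across-gene ranks to standard-normal quantiles, $(r - 0.5)/n \mapsto
\Phi^{-1}$. For a regulon with normalized likelihood weights $w_i$ and
interaction modes $m_i \in [-1, 1]$, `area_nes()` computes the one-tail
enrichment score $ES = \sum_i w_i m_i s_i$ and standardizes it against its
analytic null. Under a random signature the regulon's targets are a simple
random sample *without replacement* from the sample's $N$ signature values,
so

$$ \mathrm{Var}(ES) = \sigma^2 \left[ \left(1 + \tfrac{1}{N-1}\right)
   \sum_i w_i^2 \;-\; \tfrac{(\sum_i w_i m_i)^2}{N-1} \right], $$

with $\sigma^2$ the population variance of the signature column. As
$N \to \infty$ this converges to the independent-normal variance
$\sum_i w_i^2$, but at desk scale (tens of genes) the finite-population form
matters: with 50 genes and 10 targets the iid formula overstates the null SD
by ~12%, while the form above keeps the NES tail within Monte-Carlo error of
an empirical permutation null. This is a deliberately simplified one-tail
statistic — no three-tail decomposition and no pleiotropy/shadow correction —
because activity is used here only as a correlate of LV expression, for
which the ranking behavior is what matters.

`metaviper_consensus()` integrates activity matrices from several regulon
networks. The default rule keeps, per (protein, sample), the value of
maximum absolute NES — a deterministic reading of "consensus across
networks" that preserves the strongest evidence and records which network
supplied it; an |NES|-weighted average is available as an alternative rule.
`correlate_activity_lv()` computes the Spearman correlation of every
(LV, protein) pair and counts, per LV, the proteins with $r$ above a
threshold (default 0.65, the convention used in this analysis family).

## LV clusters and drug-target enrichment

`cluster_lvs()` clusters LV rows of the LV × protein correlation matrix by
agglomerative hierarchical clustering (Euclidean distance, complete linkage
— the defaults of the heatmap tooling this analysis descends from) and cuts
the tree at `k` (default 5). `consensus_protein_ranking()` averages each
protein's correlation over a cluster's LVs. `drug_enrichment()` runs
preranked set enrichment of drug-target sets against that consensus ranking:
the weighted Kolmogorov–Smirnov running-sum statistic with weight exponent 1,
p-values from random placements of the set within the ranking (10,000 by
default; an exhaustive enumeration mode covers tiny universes exactly),
one-sided toward positive enrichment because only positively enriched drugs
are actionable calls, and BH adjustment across drugs with significance at
q < 0.05 and ES > 0. `cluster_expression_by_type()` summarizes each
cluster's mean LV score per sample against tumor type.

## Variant association

`lv_variant_association()` restricts to variant-assayed samples, drops
silent/non-coding variant classes (configurable), and for every gene with at
least `min_mutated` carriers (default 3; 1 is allowed to mirror
single-sample-driven hits) tests each LV with a two-sided Wilcoxon rank-sum
— exact when both arms have ≤ 25 samples and no ties, otherwise the normal
approximation with tie correction — followed by BH across all (gene, LV)
pairs (default call threshold q < 0.01). The rank-sum test is our choice:
it is robust at the 3-vs-37 group sizes this data produces and consistent
with the nonparametric choices elsewhere in the workflow; a feasibility
caveat is that BH-corrected discovery at q < 0.01 across hundreds of LVs
requires p below ~$10^{-4.5}$, which small balanced arms cannot reach under
an exact rank-sum regardless of effect size (the minimum two-sided p for
8-vs-8 arms is $2/\binom{16}{8} \approx 1.5\times10^{-4}$).

## The synthetic cohort generator

`gen_model()` draws loadings as $|N(0,1)|$ masked by Bernoulli(sparsity) —
qualitatively matching PLIER's non-negative sparse loadings; no generative
recipe exists for the real model, so this is a stated stand-in, not an
estimate. `gen_cohort()` simulates $Y = ZB + \varepsilon$ with standard
normal LV scores, plants `planted_per_class` LVs per tumor class (disjoint
sets) shifted by `effect_size` SD in that class's samples, Gaussian gene
noise (default SD 0.5), and an additive log2 batch offset on a fraction of
genes that grows per study — additive in *gene* space, not LV space, because
that is where batch structure is observed and what projection is expected to
attenuate. Class labels use the four NF1 tumor-type names so reports mirror
the real analysis. Default study conditions at acceptance scale are four
classes × 15 samples, 5 planted LVs per class at 3 SD, noise SD 0.5 — a
regime where the planted signal is strong but the gene-space noise and the
projection step are both active; the demo fixture
(`write_demo_inputs()`) instead mirrors the real collection's class
imbalance (cNF-heavy) at a smaller size. What the generator does *not*
emulate: read-level noise, realistic mutational signatures, gene-gene
correlation beyond the loading structure, or per-class variance differences
in LV scores (the real per-class variance structure is unknown; scores are
homoscedastic by construction). Passing tests therefore demonstrate the
*procedures* are correct and calibrated, not that effect sizes in real
cohorts are detectable.

`gen_variants()` plants carrier sets whose LV scores are shifted via
`apply_variant_effects()` (in LV-score SD units) plus Bernoulli background
calls; `gen_regulons()` draws signed-mode, weighted targets;
`gen_drug_sets()` plants one drug whose targets come from the top stratum of
a protein ranking; `gen_immune_mixture()` draws Dirichlet mixing fractions
and produces both a linear mixture view (for deconvolution) and a log2
marker block linear in the owning type's fraction (for marker scores). All
generators are pure functions of their arguments including the seed.

## Numerical choices and problem sizes

* All stochastic steps take explicit seeds; the pipeline fans a single
  global seed out to per-stage seeds by fixed offsets, so stages are
  independently reproducible and `run_all()` reruns are byte-identical
  (verified by MD5 manifests).
* Ties: LV deduplication keeps the earlier-indexed LV; feature rankings and
  top-variable-LV reports break ties by id; hyperparameter ties prefer
  smaller `ntrees`, then smaller `mtry`.
* Degenerate inputs: zero-variance genes are flagged and zeroed;
  constant vectors yield `NA` correlations excluded from BH and counts;
  all-equal signature columns are zeroed with a warning; resamples missing
  a class are redrawn (bounded); degenerate Mood tables return p = 1.
* Test and acceptance runs use scaled-down sizes chosen to keep the planted
  effects comfortably detectable: 600 genes × 200 LVs with 60 samples and a
  100-resample ensemble for feature selection; 10,000 draws for empirical
  nulls; 20-seed loops for calibration checks.

## Worked example

```{r example, eval = FALSE}
model <- gen_model(n_genes = 600, n_lvs = 200, sparsity = 0.1, seed = 11)
cohort <- gen_cohort(model, c(cNF = 15, MPNST = 15, NF = 15, pNF = 15),
                     planted_per_class = 5, effect_size = 3,
                     noise_sd = 0.5, seed = 12)
B <- project_lv(model, zscore_genes(cohort$expression))
split <- split_model_test(cohort$metadata, seed = 13)
labels <- setNames(cohort$metadata$tumor_type, cohort$metadata$sample_id)
ens <- run_ensemble(B[, split$model_ids], labels[split$model_ids],
                    config = ensemble_config(n_iterations = 100, seed = 14),
                    ntrees = 500)
sel <- select_top_features(ens, top_k = 40)
autoplot(ens)
```

## Known limitations

* The deconvolution arm is non-negative least squares, not support-vector
  regression; absolute-mode scores and permutation p-values are out of
  scope.
* Regulon activity is a one-tail statistic without pleiotropy correction;
  it is intended for correlation with LVs, not for standalone
  protein-activity calls.
* The synthetic generator's noise model is homoscedastic and study offsets
  are deterministic per study; real batch effects are messier.
* The batch-effect statistic detects a *difference* in normalized
  within-study distance distributions between spaces; mapping its direction
  onto "which space is cleaner" depends on whether batch or biology
  dominates each space and should be read together with the PCA plots.
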