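---
title: "Methods: collagen-linked angiogenesis analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collagen-linked angiogenesis analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angiocol)
```

`angiocol` quantifies the association between intratumoral collagen and
angiogenesis across three data modalities — bulk expression cohorts,
single-cell counts, and spatially resolved spots — and classifies tumors
into immuno-collagenic subtypes. This vignette is the package's account of
the statistical machinery: what each method assumes, which parameters
matter, how degenerate inputs are handled, and which design choices were
genuinely open.

## Signature scoring

### Single-sample enrichment

Per-sample gene-set activity is the integrated, rank-weighted running sum
of the ssGSEA family. Within a sample, genes are ranked by descending
expression with average ranks for ties; walking down the ranked list,
in-set genes step the hit curve up by $(G - r_g + 1)^\alpha$ (normalised by
the in-set total) and out-of-set genes step the miss curve up by
$1/(G - k)$; the score is the sum of the hit-minus-miss difference over all
$G$ positions. Tied positions in the walk are ordered by gene ID, so the
score is a pure function of the expression *ranks* and the gene
identities: it is invariant to any strictly monotone per-sample transform
and to row permutations of the matrix (both properties are tested).

This estimator was chosen over kernel-smoothed ECDF variants because it is
fully specifiable and checkable against a position-by-position enumeration
oracle; every downstream use in the pipeline (correlations, group
contrasts, averaging into a composite) depends only on a per-set monotone
score, not on a particular estimator's scale.

* `alpha` (default **0.25**): the conventional ssGSEA rank-weight exponent.
  `alpha = 0` reduces to the unweighted Kolmogorov–Smirnov walk.
* `min_overlap` (default 2): sets with fewer matrix genes raise an error
  naming the offending set rather than returning a meaningless score.
* Gene matching is exact and case-sensitive; alias harmonisation is the
  caller's responsibility.

### Endothelial deconvolution

The deconvolution-based endothelial abundance solves, per sample on the
linear scale ($2^x - 1$ for log2 input), the constrained least-squares
problem $\min \|Rf - b\|_2$ s.t. $f \ge 0,\ \sum f \le 1$ over reference
cell-type profiles. The solver enumerates candidate active sets (with and
without the sum constraint binding) and keeps the feasible minimum — exact
for the small reference panels this problem uses (a handful of cell
types), and verified against a coarse-to-fine grid search over the
constrained simplex at step $10^{-3}$. A rank-deficient reference produces
a warning and a pseudo-solution. The returned fraction is always in
$[0, 1]$ by construction.

### The composite angiogenesis score

Six features enter the composite: four angiogenesis pathway enrichment
scores, the deconvolution endothelial fraction, and a marker-based
endothelial enrichment score. Because enrichment scores and fractions live
on different scales, each feature is z-scored across samples before
averaging (`standardize = TRUE`, the default); raw averaging is available
for cohorts where the features are already commensurate. This scaling
choice was genuinely open — simple averaging of heterogeneous features is
also defensible when all six are enrichment-like — so both behaviours are
implemented and the default documented. A feature constant across samples
carries no information and is dropped with a warning rather than
propagating NaNs.

## Immuno-collagenic subtyping

The histologic rule is applied verbatim: soft & hot = TIIC ≥ 3 and
fibrosis 0–1; armored & cold = TIIC ≤ 2 and fibrosis 2–3; quiescent =
TIIC ≤ 2 and fibrosis 0–1. The only combination outside those rules
(TIIC ≥ 3 with fibrosis 2–3) is emitted as `unclassified`; an exhaustive
sweep over TIIC 0–5 × fibrosis 0–3 is a test fixture.

The transcriptomic rule orders the two scores: immune-high samples are
soft & hot; among immune-low samples, collagen-high ones are armored &
cold, the rest quiescent. Immune-high *and* collagen-high samples are rare
and fold into soft & hot by default (immune dominates), with
`high_high = "unclassified"` as the auditable alternative. Published
cutpoints for these scores are cohort conventions that are not
re-derivable here, so cutpoints are explicit inputs with two supported
derivations:

* **median** — the default, appropriate when subtypes are expected at
  roughly equal prevalence;
* **largest gap** (`derive_cutpoint(x, "largest_gap")`) — the midpoint of
  the widest gap between consecutive sorted scores inside a central
  quantile window (15–95%). For well-separated bimodal scores this tracks
  the true between-cluster boundary even when the realized subtype
  prevalence drifts from its expectation, which a fixed quantile cannot do;
  it is the derivation used by the planted-recovery checks. For weakly
  separated scores the largest gap is noise-driven and the median is the
  safer choice.

Discrimination is summarised by the rank-based AUC (the probability a
random positive outscores a random negative, ties counting one half),
which equals brute-force pairwise enumeration exactly, including ties.
Group contrasts use one-way ANOVA with Tukey HSD or Kruskal–Wallis with
Dunn's pairwise z-tests. Dunn's tests are Holm-adjusted: the adjustment
method is not dictated by the pairwise procedure itself, and Holm controls
the family-wise error without independence assumptions. Zero-variance
input (all values identical) returns statistic 0 and p = 1 rather than
NaN.

## Differential expression and enrichment

Genes are tested with Welch's two-sample *t* on log2 values; the
linear-scale fold change is $2^{\bar{x}_A - \bar{x}_B}$ and a gene is
flagged when $p < 0.05$ *and* FC ≥ 1.5 (two-sided by default, direction
flags available). The gate is deliberately on raw p-values — it is a
threshold rule, not an FDR claim — and a Benjamini–Hochberg column is
emitted alongside for users who want one. Moderated-variance estimators
would change individual p-values but not the nature of the gate; Welch's
*t* keeps the per-gene null exact under normality and calibrated in the
package's null simulations. Genes with zero variance in both groups get
p = 1 when means agree (p = 0 otherwise).

Preranked GSEA uses the classic weighted Kolmogorov–Smirnov enrichment
score (weight exponent 1) and a *gene-set permutation* null: random sets
of equal size drawn from the ranking, which is deterministic under a seed
and appropriate for desk-scale reproducibility (phenotype permutation
requires the sample-level matrix and much larger compute). NES divides ES
by the mean |null ES| of matching sign, and
$p = (1 + \#\{\text{same-sign null} \ge \text{observed}\}) / (1 +
\#\text{same-sign})$, so p never falls below $1/(n_{perm}+1)$. The ranking
metric for cohort contrasts defaults to the signed *t* statistic (the
`deg.csv` column fed to `gsea_preranked` in `run_pipeline`); log-FC
ranking is available by passing a different vector.

Over-representation is the one-sided hypergeometric tail with a
Haldane-corrected odds ratio when a margin cell is zero; it matches exact
combinatorial sums on all universes up to 30 in tests.

## Single-cell analysis

QC keeps a cell iff mitochondrial fraction ≤ 0.10 **and** 200 ≤ detected
genes ≤ 5000; only strict exceedance excludes, so boundary cells (exactly
10%, exactly 200 or 5000 genes) are kept. Metrics are recomputed from the
count matrix (mitochondrial genes by the configurable `MT-` prefix), which
makes the filter idempotent. Normalization is library-size scaling to a
common total plus log1p; the embedding is PCA on the top 4000
variable genes (by variance of the log values), 40 components by default,
with optional per-batch centering of the embedding as a lightweight
batch-effect control. Clustering is Louvain community detection on a kNN
graph (k-means fallback with a fixed seed), and clusters are annotated by
the cell type whose markers have the highest mean z-scaled expression,
ties breaking lexicographically with a warning.

The ligand–receptor test scores an ordered type pair (A→B) and gene pair
(L,R) as $\tfrac12(\overline{L}_A + \overline{R}_B)$ on normalized
expression, with a 10% expressed-fraction gate in the respective clusters
(combinations failing the gate are floored to score 0, p = 1). The null
permutes cell-type labels; the add-one estimator keeps p ≥
$1/(n_{perm}+1)$. Cells are canonicalised by ID before permutation so the
result is invariant to column order. The 10% gate follows the convention
of the standard interaction-screening tools; multi-subunit receptor
complexes are out of scope. Type-I error at α = 0.05 under label
exchangeability is verified to lie in [0.03, 0.07] at 1000 permutations
over 200 null pairs.

## Spatial proximity

The proximity statistic is the nearest-neighbour Euclidean distance from
each source spot (endothelial) to the nearest spot of a target type, with
self-exclusion for same-type queries. Nearest-neighbour was preferred over
mean pairwise distance because it operationalises "positioned closer to"
robustly: mean pairwise distance is dominated by global field geometry and
carries almost no co-localization signal (a planted-structure simulation in
the test suite makes this concrete); the mean-pairwise variant remains
available behind `distance = "mean"`. Co-localization is assessed by
two-sided Mann–Whitney (normal approximation, tie-corrected) between
distance-to-reference and distance-to-other, either pooled over all other
types or per type. Complete ties (e.g. all spots coincident) return p = 1.

One calibration caveat is documented rather than hidden: nearest-neighbour
distances shrink with target abundance, so the *pooled* comparison is only
calibrated under no-co-localization when the reference set and the pooled
other set have comparable sizes. The package's null-calibration checks use
matched spot counts; direction-of-effect conclusions (median distance to
fibroblasts below median distance to others) are insensitive to this.
Samples are never pooled across arrays — coordinates are not comparable —
so multi-sample reports are per-sample tables.

## Survival statistics

Markers are dichotomized at the median with values *at* the median going to
the high group (on 65 distinct values this yields 32 low / 33 high); the
mirrored convention is a flag. Kaplan–Meier estimation and the log-rank
test delegate to the `survival` package (product-limit estimator;
observed-minus-expected with hypergeometric variance, k−1 df for k
groups), with tied censoring placed after events at the same time, and are
cross-checked in the tests against a hand-built event-table oracle.
Response-rate tables use the chi-square homogeneity test without
continuity correction, falling back to Fisher's exact test when any
expected cell is below 5 (Cochran's rule, applied strictly: expected
exactly 5 stays chi-square).

## What the synthetic generators emulate

The generators produce every input the pipeline consumes, with planted,
tunable ground truth:

* **Bulk** (`gen_bulk_cohort`): log2-scale Gaussian expression (the
  substrate of processed cohort matrices; no count layer) with disjoint
  collagen / immune / angiogenesis / background gene blocks and three
  planted subtypes. Per-sample collagen activity is
  `collagen_effect` × I(armored & cold) plus a small continuous jitter
  (sd = effect/5), and the angiogenesis-program shift is `angio_coupling`
  times that activity — so the collagen–angiogenesis correlation is a
  smooth, planted quantity rather than a pure group contrast. Defaults
  (400 samples, 50/25/25% subtypes, effects of 2–3 log2 units, noise sd
  0.5) give cleanly separated programs at realistic cohort size.
* **Single-cell** (`gen_sc_dataset`): negative-binomial counts over
  type-specific marker blocks and a shared housekeeping block;
  mitochondrial genes are a named `MT-` block filled to a per-cell target
  fraction so QC structure is planted exactly; ligand/receptor genes are
  elevated only in their source/target type and kept under the 10%
  expressed-fraction gate elsewhere.
* **Spatial** (`gen_spatial_sample`): fibroblast and other spots uniform
  on a square field; endothelial spots Normal(anchor, `coloc_sd`²) around
  random fibroblast anchors, clipped to the field; `coloc_sd = Inf`
  encodes uniform (null) placement.
* **Survival** (`gen_survival`): exponential event times per group with
  independent exponential censoring — the simplest mechanism with
  closed-form expectations.

What they deliberately do **not** emulate: realistic expression profiles
or gene–gene correlation beyond the planted blocks, doublets, ambient
RNA, batch-specific biology, spatial image structure, or non-proportional
hazards. Passing the planted-recovery and calibration tests therefore
demonstrates that the *statistical machinery* behaves as specified — not
that any biological conclusion transfers to a particular real dataset.

## Problem sizes and numerical conventions

The test suite and acceptance script run at sizes chosen to make
Monte-Carlo bands tight while keeping a laptop-scale footprint: 400-sample
cohorts for recovery, 1000-gene null cohorts for the differential
expression rate, 500 replicates for each p-value uniformity check
(Kolmogorov distance < 0.1), 1000 permutations for the ligand–receptor
type-I check over 200 null pairs, and 2000-spot fields for the distance
oracle. Seeds are explicit everywhere; every generator restores the
caller's RNG state. Ranking ties use average ranks; walk-order ties break
by gene ID; permutation p-values use add-one estimators; degenerate inputs
(zero variance, complete ties, empty groups) return the documented
constants or located errors rather than NaN.

## Limitations

* The enrichment, deconvolution and interaction statistics are method
  *substitutions* of the same statistical roles used in practice
  (kernel-ECDF single-sample scorers, reference-panel deconvolution
  suites, curated interaction databases); scores are monotone analogues,
  not numerically interchangeable with any specific tool's output.
* Transcriptomic subtype cutpoints are conventions; results should be
  reported with the cutpoint derivation alongside.
* The spatial test treats one annotation per spot; deconvolved
  multi-label spots are out of scope.
* No Cox regression, RECIST adjudication or interval censoring; survival
  support covers KM/log-rank/response-rate designs.
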