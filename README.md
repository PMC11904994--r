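# angiocol

Tumors that wall themselves in dense collagen while excluding immune cells
("armored & cold" tumors) are a clinically distinct microenvironment
subtype: they respond poorly to immunotherapy, yet their stroma is highly
angiogenic, which makes anti-angiogenic therapy an attractive alternative.
`angiocol` implements the computational pipeline for studying that link
between intratumoral collagen and angiogenesis across bulk, single-cell and
spatial transcriptomics, for researchers analysing tumor-microenvironment
cohorts:

* **Signature scoring** — single-sample gene-set enrichment (an ssGSEA-family
  rank statistic), constrained least-squares endothelial deconvolution, and
  a composite angiogenesis score averaging six angiogenesis-related
  features (four pathway enrichment scores plus two endothelial-abundance
  estimates).
* **Immuno-collagenic subtyping** — quiescent / armored & cold / soft & hot
  calls from transcriptomic collagen and immune scores, or from pathology
  TIIC and fibrosis scores (TIIC ≥ 3 & fibrosis 0–1 → soft & hot; TIIC ≤ 2 &
  fibrosis 2–3 → armored & cold; TIIC ≤ 2 & fibrosis 0–1 → quiescent), with
  ROC/AUC discrimination and ANOVA/Kruskal–Wallis group contrasts.
* **Differential expression and enrichment** — per-gene Welch *t* with the
  *P* < 0.05 and FC ≥ 1.5 gate, preranked GSEA (weighted Kolmogorov–Smirnov
  running sum, set-permutation null, NES), hypergeometric
  over-representation.
* **Single-cell analysis** — QC (mitochondrial fraction ≤ 10%, 200–5000
  detected genes), normalization, PCA, graph clustering and marker
  annotation, and a CellPhoneDB-style ligand–receptor label-permutation
  test with per-type-pair significant-interaction counts.
* **Spatial proximity** — nearest-neighbour Euclidean distance from
  endothelial spots to fibroblast versus other spots, Mann–Whitney
  co-localization tests, per-sample summaries.
* **Survival statistics** — median dichotomization of continuous markers
  (e.g. microvessel density), Kaplan–Meier curves, log-rank tests,
  response-rate contrasts.
* **Synthetic data generators** — every input above, with planted ground
  truth (subtype structure, collagen–angiogenesis coupling,
  ligand–receptor pairs, spatial co-localization, hazard differences), so
  the whole pipeline is testable without external downloads.

## The core statistics

For a sample with genes ranked by descending expression (average ranks for
ties), the enrichment score of gene set *S* with |*S*| = *k* among *G* genes
is the integrated running sum

```
score = Σ_{i=1..G} [ P_hit(i) − P_miss(i) ]
P_hit(i)  = Σ_{g ∈ S, rank(g) ≤ i} (G − rank(g) + 1)^α / Σ_{g ∈ S} (G − rank(g) + 1)^α
P_miss(i) = #{g ∉ S, rank(g) ≤ i} / (G − k)
```

with weight exponent α = 0.25. The composite angiogenesis score is the mean
of the six (z-scored) angiogenesis features. The endothelial fraction per
sample solves `min ‖R f − b‖₂` subject to `f ≥ 0`, `Σf ≤ 1` over reference
cell-type profiles `R` on the linear scale. The ligand–receptor score for an
ordered cell-type pair (A→B) and pair (L,R) is `½(mean L in A + mean R in B)`
with significance from permuting cell-type labels and an expressed-fraction
gate of 10%.

## Worked example

```r
library(angiocol)

cohort <- gen_bulk_cohort(bulk_sim_config(
  n_samples = 400, n_genes = 500, collagen_effect = 3,
  immune_effect = 3, angio_coupling = 1, seed = 42))
ref <- synthetic_reference_profiles(cohort$programs, rownames(cohort$expr),
                                    cohort$baseline)
panel <- build_feature_panel(cohort$expr, cohort$angio_sets,
                             cohort$programs$endothelial_markers,
                             cohort$programs$collagen, cohort$programs$immune,
                             ref = ref)
calls <- assign_transcriptomic_subtype(
  panel$collagen_score, panel$immune_score,
  collagen_cut = derive_cutpoint(panel$collagen_score, "largest_gap"),
  immune_cut = derive_cutpoint(panel$immune_score, "largest_gap"))
table(calls$subtype)
#>    quiescent armored_cold     soft_hot unclassified
#>          201          103           96            0

correlate(panel$collagen_score, panel$angiogenesis_score)
#> r = 0.980, p = 8.38e-280

group_contrast(panel$angiogenesis_score, calls$subtype)$summary
#>          group   n   mean    sd
#>      quiescent 201 -0.431 0.376
#>   armored_cold 103  1.408 0.291
#>       soft_hot  96 -0.608 0.435
```

The 400-sample synthetic cohort plants three subtypes (50/25/25%); the
calls recover 99% of the planted labels, the collagen score correlates with
the composite angiogenesis score at r = 0.98 (the planted coupling), and
the armored & cold group carries the highest angiogenesis score —
discriminating it at AUC = 1.00 here. Downstream, the armored-&-cold-vs-rest
contrast flags 140 of 500 genes at *P* < 0.05 and FC ≥ 1.5 (the planted
collagen, angiogenesis and immune programs), and preranked GSEA scores the
first angiogenesis pathway set at ES = 0.83 (*p* = 0.034 at 1000
permutations).

File-based workflows use `run_pipeline(pipeline_config(...))`, which reads
expression TSV, GMT gene sets, MTX single-cell triplets, spot and survival
CSVs and writes provenance-headed CSV outputs; reruns with the same
configuration are byte-identical.

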