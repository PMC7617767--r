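---
title: "Methods: signature derivation, scoring and enrichment in vmsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature derivation, scoring and enrichment in vmsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmsig)
```

## Scope and scientific setting

Vasculogenic mimicry (VM) is the formation of perfused, matrix-lined
pseudo-vessels by tumor cells that ectopically express endothelial genes.
Studying this phenotype from transcriptomes requires a small, recurring set
of computational pieces: deriving transcription-factor target signatures
from differential-expression (DE) contrasts, scoring those signatures per
patient (bulk cohorts) and per cell (scRNA-seq), ranking whole
transcriptomes against a signature, and testing gene sets against those
rankings. `vmsig` implements that machinery as pure functions over plain
containers (data frames, base matrices, `Matrix` sparse matrices), with
seeded synthetic-data generators so every stage is verifiable offline.

Upstream steps are deliberately out of scope: alignment and counting, DE
model fitting (DESeq2/limma tables are *inputs*), single-cell clustering
and integration (cluster labels are inputs), and survival analysis.

## Signature derivation

Derivation consumes DE tables (`gene`, `log2fc`, `pvalue`, `fdr`) and
applies a cascade of strict filters, all recorded in
`derivation_config()`:

* `derive_top_up()` — among genes with FDR < `alpha_sig` (default 0.05)
  and positive fold change, the `top_n` (default 100) by descending
  log2 fold change. Ranking is by fold change, not significance, because
  the downstream ranked lists are fold-change based; a significance
  ranking would be a config alternative, not a different contract.
* `derive_concordant()` — genes significantly up under factor
  over-expression *and* significantly down under knockdown. "Significant"
  is FDR < 0.05; the threshold is surfaced in the config rather than
  hard-coded.
* `derive_core()` — concordant genes additionally required to show
  log2FC > 0.5 in both auxiliary comparisons and FDR < 1e-5 (positive
  fold change) in the ranking comparison, then the top `core_k = 5` by
  ranking-comparison fold change. Genes absent from an auxiliary table
  fail that filter: absence is treated as lack of evidence, the
  conservative reading.

All comparisons are strict (`>` 0.5, `<` 30%, `<` 1e-5) exactly as the
thresholds are written; boundary values are excluded. Every ranking tie is
broken by gene identifier ascending in the C locale — determinism over
arbitrariness, and independent of the session locale.

`refine_by_cluster_stats()` implements the endothelial-set refinement:
keep genes with log2FC > 0.5 between endothelial and fibroblast clusters
and detected in < 30% of fibroblast cells. `subtract_gene_set()` and
`map_orthologs()` cover mesenchymal-gene removal and explicit
mouse-to-human symbol mapping (identifiers are otherwise opaque,
case-sensitive strings — no implicit case folding).

## Scoring

**Mean-Z cohort scores.** `zscore_genes()` standardises each gene across
samples (divisor `n - 1`; zero-variance genes are removed with a warning,
since they carry no ranking information and would divide by zero).
`mean_z_signature_score()` averages the z-values of the signature genes
present in the matrix, per sample. A signature covering the whole universe
has mean score zero across samples by construction — a conservation
property the tests assert.

**Per-cell AUC scores.** `aucell_score()` is a rank-recovery score: each
cell's genes are ranked by decreasing expression, and with cutoff
`m = ceiling(auc_max_frac * N)` (default 10% of the universe) and `g`
signature genes in the universe,

$$\mathrm{auc} \;=\; \frac{\sum_{k=1}^{m} H(k)}{\sum_{k=1}^{m} \min(k, g)},$$

where `H(k)` counts signature genes at rank ≤ k. The denominator is the
perfect-recovery area, so the score lives in [0, 1], reaching 1 iff the
signature occupies the top `g` ranks and 0 iff no signature gene enters
the top `m`. The ceiling in `m` and the perfect-recovery normalisation are
contract choices fixed here and pinned by an independent brute-force
oracle in the test suite. Ties — dominated by the zeros of sparse cells —
break by gene identifier by default; a seeded random tie mode is provided
for sensitivity checks, but the deterministic mode is the default because
reproducibility matters more than tie symmetry at the scale of a 10%
cutoff. Because the score only sees ranks, it is invariant to any
within-cell monotone transform, which is why the simple log normalisation
below is sufficient upstream.

**H-score.** `h_score()` is the standard immunofluorescence summary
`100 * (1 f_w + 2 f_m + 3 f_s)` over all nuclei (negatives in the
denominator), a convex combination scaled to [0, 300].

## Pre-ranked GSEA

`enrichment_score()` implements the weighted Kolmogorov–Smirnov walk: with
matched set S of size `N_S` and `N_R = sum_{j in S} |r_j|^p`, the running
statistic accumulates `|r_i|^p / N_R` at hits and `1/(N - N_S)` at misses;
the enrichment score is the deviation of maximal absolute value. Numerical
choices:

* A tie between equal-magnitude positive and negative extrema resolves to
  the positive one. The comparison carries a 1e-12 tolerance so
  mathematically exact ties (symmetric walks) resolve identically
  regardless of floating-point summation order.
* With `weight_p = 0` the statistic reduces to the classical unweighted KS
  statistic; with all-zero weights the hit increment degenerates to `1/g`.
* The implementation evaluates the walk only at hit positions (O(g) per
  set after weight lookup); the test suite checks it exhaustively against
  a full O(N) walk for all subsets of lists up to N = 8 and on random
  instances.

`gsea_preranked()` uses gene-set permutation — the only null available to
pre-ranked input: `n_perm` (default 1000) random same-size draws from the
ranked universe, seeded. NES divides ES by the mean absolute same-sign
null ES; the nominal p is the add-one-corrected same-sign tail fraction
`(b + 1)/(n + 1)`, which cannot be zero; the FDR q follows the
normalised-null ratio procedure of the original GSEA method (pooled null
NES tail fraction over observed NES tail fraction, clamped to [0, 1]).
Sets are size-filtered on their matched size (defaults [5, 2000]).
`signed_log10_q()` compresses a result to `sign(es) * -log10(q)` with
floor `1/(n_perm + 1)`, the resolution limit of the permutation FDR.

## Cohort ranking metrics and group comparison

`rank_by_correlation()` mirrors the discovery analysis for genes
travelling with a small core signature: z-score, per-sample mean-Z core
score, then per-gene Pearson (default) correlation of the raw expression
row with the score vector. Core genes stay in the list by default — their
high self-correlation is the intended positive control — with
`exclude_core` available. Whether the correlated rows are raw or z-scored
is exposed (`use_zscored`); for Pearson the per-gene coefficient is
unchanged by the per-gene affine rescaling, so the default follows the
simpler raw convention. `rank_by_median_diff()` (target-group median minus
global median) and `rank_by_mean_z_diff()` (difference of group mean
z-scores, the proteomics convention) cover the panel-contrast metrics.

`compare_groups_ranksum()` is the two-sided Wilcoxon rank-sum test via
`stats::wilcox.test`: exact enumeration when `min(n) <= 8` and tie-free,
otherwise the tie-corrected normal approximation with continuity
correction. It warns below a total of 8 samples, where the test has
essentially no power.

## The single-cell endo-high pipeline

`sc_config()` records the study conditions: cells kept with 200–9000
unique features (inclusive bounds) and mitochondrial percentage strictly
below 10; features kept when detected in ≥ 5 cells of at least one sample.
The per-sample feature rule is the lenient union — the filter was applied
per sample before merging, so a feature passing anywhere survives.
`qc_filter()` is idempotent. Mitochondrial percentage arrives precomputed
in the annotation (the upstream counting pipeline defines it); the
synthetic generator computes it exactly from planted mitochondrial genes.

`lognormalize()` is `log1p` of library-size-scaled counts (scale 1e4).
It replaces regression-based variance stabilisation, which belongs to the
out-of-scope upstream; the substitution is safe here because the AUC
scoring that consumes it is rank-based within each cell and therefore
insensitive to any monotone per-cell transform.

`classify_tumor_clusters()` calls a cluster tumor when strictly more than
20% of its cells carry the CellTag lineage marker.
`classify_endo_high()` takes the top `ceiling(0.05 * n)` cells by
endo-score within the selection universe (the `within` argument supports
restricting to, e.g., treated-arm tumor cells when control scores are
globally lower); the threshold returned is the lowest selected score.
`rank_markers()` contrasts endo-high cells against the remaining tumor
cells: the metric is `log2` of linearised group means with a small rate
pseudocount (default 1e-4, one count per scaled library) — pseudocount
conventions differ between marker tools, so ours is explicit — plus
per-gene rank-sum p-values and BH q-values. No minimum-expression
prefilter is applied: silent gene dropping would bite the downstream
enrichment coverage. `pseudo_bulk()` sums cluster counts per sample and
conserves totals exactly.

## Synthetic data: what it emulates and what it does not

The generators are pure functions of their spec (including the seed) and
return ground-truth sidecars sufficient to compute precision and recall
for every downstream classification.

**`gen_de_quartet()`** (2000 genes) plants `n_core = 5` genes passing
every derivation filter with margin (ranking-table fold changes 3.1–3.5,
p-values at `fdr_core / n_genes` so BH q stays below 1e-8), 45 concordant
decoys that each fail exactly one core filter (split across the two
auxiliary fold-change filters and the ranking FDR filter, so each filter
is exercised), and null genes with uniform p-values and N(0, 0.2) fold
changes. A null gene would need p < ~3e-8 in the ranking table plus
concordance in two further tables to contaminate the core — negligible at
this scale.

**`gen_cohort()`** (3000 genes × 500 samples) drives a 50-gene module
with a latent factor: module rows are
`loading * f + sqrt(1 - loading^2) * noise`, so module genes have unit
variance and within-subtype pairwise correlation `loading^2` (0.64 at the
default loading 0.8). The aggressive-subtype shift (1 SD) is applied to
the latent factor mean rather than to the module rows directly: that keeps
the module's correlation structure interpretable while still elevating the
module score in the aggressive group, matching how a subtype-enriched
program behaves in real cohorts.

**`gen_sc_dataset()`** draws negative-binomial counts (dispersion 0.5,
i.e. size 2; per-gene baseline means log-normal with median 0.2) for 1500
tumor, 300 endothelial and 300 fibroblast cells across 2 replicate
samples — 2100 cells total. A 100-gene endothelial signature is elevated
4-fold in endothelial cells and in a planted 5% endothelial-like tumor
fraction, which co-elevates a 50-gene program set 3-fold (the planted
analogue of a TF program, sharing the endothelial elevation rather than
replacing it — the premise is ectopic endothelial expression in tumor
cells). Ten mitochondrial genes (20-fold baseline mean, as housekeeping
genes) define `mito_pct` exactly; one CellTag marker is detected in 60%
of tumor-lineage cells. The universe holds 10000 genes so that the
9000-feature QC bound is attainable: nine QC violators (three per rule)
are planted among non-endothelial-like tumor cells, each failing exactly
one rule, which makes filter reports exactly predictable while keeping
the 2100-cell total.

The generators do **not** emulate ambient RNA, doublets, batch effects,
cell-cycle structure, or the depth and cell counts of the real deposited
datasets. Passing the recovery tests therefore demonstrates correctness
of the pipeline's logic under its stated statistical assumptions, not
robustness to the full noise structure of real tissue data.

## Problem sizes and verification

The test suite's heavier checks run at deliberately chosen desk scales:
the AUC oracle equivalence at 200 random instances with universes ≤ 50
genes; ES exhaustively for all subsets of lists up to N = 8; GSEA null
calibration with 200 random 20-gene sets on a 1000-gene list at 1000
permutations (mean |NES| within [0.85, 1.15], nominal p uniform by KS
goodness of fit); the full single-cell recovery at the default 2100-cell
spec; rank-sum calibration at 1000 null simulations and power at 100
simulations of a 1 SD shift with 30 vs 30 samples.
`scripts/acceptance.R` recomputes all of these from scratch under a
caller-supplied seed and writes the resulting numbers as JSON.

## Known limitations

* The permutation FDR inherits the granularity of `n_perm`; q-values of
  exactly 0 mean "below resolution", which is why `signed_log10_q()`
  floors at `1/(n_perm + 1)`.
* `aucell_score()` densifies one cell column at a time; universes far
  beyond ~10^5 genes × 10^5 cells would warrant a compiled ranking path.
* The marker test is a per-gene rank-sum on normalised values; it does
  not model per-sample pseudo-replication (use `pseudo_bulk()` plus a
  bulk DE tool when replicate-aware inference is needed).
* `rank_by_correlation()` assumes the score vector is meaningful for at
  least 3 samples and excludes zero-variance genes rather than imputing.
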