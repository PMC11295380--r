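---
title: "Methods: malignant-cell subtype discovery and composition heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: malignant-cell subtype discovery and composition heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hccsubtype)
```

## The model

HCC malignant cells are treated as a mixture of three expression programs:
a metabolism program (marked by ARG1, ALDOB), a proliferation program
(TOP2A, STMN1, MKI67), and an EMT program (S100A6, S100A11, plus the
cancer-stem-cell markers EPCAM, CD24, KRT19, SOX9, PROM1, CD44, THY1,
CD47). The analysis assumes (i) each tumor cell predominantly expresses one
program, (ii) the proliferative fraction of a sample is roughly constant
across samples, and (iii) the non-proliferative mass of a sample is split
between the metabolism and EMT programs with one of them dominant, the
dominant side being a patient-level property. The pipeline's job is to
recover the per-cell program labels from counts, validate the three-class
structure with an independent clustering, and quantify the sample-level
composition structure.

## Discovery procedure

Subtype discovery is deliberately two-staged. Graph clustering
over-segments the cells into subclusters (real cohorts produce dozens);
the subclusters are then merged by transcriptome similarity: mean
log-expression profiles per subcluster, the 50 genes with the highest
across-cluster standard deviation, Spearman correlation ρ between profiles
on those genes, and average-linkage hierarchical clustering on the
distance 1 − ρ cut at three groups. Merging on profile similarity rather
than trusting the graph partition directly makes the result robust to the
clustering resolution, which is the one genuinely free parameter of the
stage.

Three choices here were open and are worth recording:

* **Top-SD gene selection** uses the *population* SD (ddof = 0) of
  *unweighted* cluster means. Weighting the means by cluster size would
  let one huge subcluster dominate the gene ranking; unweighted means
  treat subclusters as the unit of replication, which matches the intent
  of a similarity analysis *between clusters*.
* **Average linkage on 1 − ρ**: standard for correlation-based profile
  clustering; single linkage chains small clusters, complete linkage is
  unstable when one subcluster is an outlier.
* **Marker-based naming** replaces manual annotation: the group with the
  highest mean expression of each program's canonical markers takes that
  program's name, and a collision (one group winning two names) is an
  error rather than a silent guess.

## NMF consensus validation

The three-subtype claim is validated by an independent clustering route:
50 cells per sample are drawn without replacement, and the log-normalized
matrix over the union of subtype markers and HVGs is factorized at rank
k = 3 with Lee–Seung multiplicative updates minimizing squared Frobenius
error. Cells are assigned to their argmax factor and compared with the
subtype labels through the *concordance rate*: the maximal fraction of
agreeing cells over all one-to-one matchings of the class sets (exhaustive
search; both labelings are capped at six classes). Repeating this over ten
resamplings gives a median and range.

Two deviations from common defaults are intentional. NMF packages often
default to Kullback–Leibler loss; squared Frobenius was chosen because the
input here is log-space expression, where the Gaussian-flavored objective
is the natural fit and the multiplicative updates are numerically robust
(the update denominators are guarded by machine epsilon, and the loss
trajectory is asserted non-increasing on every run). And because
"concordance" between two unaligned categorical labelings is ambiguous,
the best-matching definition was fixed: it is symmetric, invariant to
class renaming, and reduces to plain accuracy when the labelings share
classes. Cells with an all-zero loading row are excluded from the
denominator rather than counted as disagreements.

## Signature scoring

One scoring engine is used for every gene-set quantity: single-sample GSEA
(the rank-weighted ECDF running-sum statistic) with the conventional
exponent α = 0.25. Genes are ranked by expression descending with stable
ties (input gene order), and the score is Σᵢ (ECDF_in(i) − ECDF_out(i))
with in-set weight rankᵅ. Normalization divides by the analytic max − min
achievable for the set size and gene count — the score of the set packed
at the top minus packed at the bottom — rather than by a permutation null,
which keeps single-entity scores deterministic and comparable across
entities. The statistic depends only on ranks, so it is invariant under
any strictly monotone transform of the expression vector; the test suite
asserts this property directly. The stemness (CSC) score uses the simpler
mean z-score form: per-gene z-scores across entities averaged over the
8-marker set, with zero-variance genes contributing 0.

## Regulon activity

Regulons (transcription-factor target sets) are *inputs*; no network
inference is performed. To suppress single-cell noise, cells are
aggregated into pseudo-cells: within each subtype the cells are randomly
permuted and chunked into disjoint groups of 20, incomplete chunks
dropped, each pseudo-cell being the group mean. Disjoint chunking (rather
than resampling with replacement) guarantees each cell contributes exactly
once, so pseudo-cells are independent given the permutation. Activity is
the recovery-curve AUC: over the top 5% of the descending expression
ranking (the established recovery-window convention), the cumulative count
of regulon genes is integrated and normalized by the maximal achievable
area, bounding the AUC in [0, 1]. Specificity uses
RSS = 1 − √JSD(P, Q) with base-2 logarithms (so JSD ∈ [0, 1]), where P is
the regulon's activity column normalized to a distribution over
pseudo-cells and Q is uniform over the pseudo-cells of one subtype.

## Composition heterogeneity

Per-sample subtype fractions live on the 2-simplex; Euclidean distance is
applied to the raw 3-vectors without transform, which keeps the magnitudes
interpretable (two samples flipping Metab↔EMT dominance are ~√2·Δ apart).
Within-patient and between-patient distance sets are compared with a
two-sided Wilcoxon rank-sum test: exact by full enumeration of group
assignments when the pooled size is ≤ 20 (the p-value is then provably
equal to the brute-force reference, which the tests check), and the
normal approximation with tie and continuity correction beyond that.
Mutation-rate tables round half-up to one decimal, matching the
convention of printed clinical percentage tables (base R's `round()`
rounds half to even, which would print 72.72…% of 16/22 correctly but
differ on exact halves).

## The synthetic cohort generator

The generator emulates exactly the structure the analysis assumes: counts
are negative-binomial with a single dispersion parameter (the standard
single-cell noise family) around per-gene log-normal baseline means;
cells of subtype *s* elevate that program's genes by `program_log_fc`
(natural log, default 2); library sizes are log-normal (sdlog 0.3 around
5000); a designated block of "MT-" genes receives a per-cell mitochondrial
fraction (Beta, mean 5%); and a configurable fraction of cells is
generated to fail QC — half by truncating the library to 100–400 counts
(< 500 detected genes), half by inflating the mitochondrial fraction to
20–50% — so the thresholds are exercised on both sides of their
boundaries.

Composition structure: each sample draws its proliferative fraction from
Beta(μκ, (1−μ)κ) with μ = 0.2 and κ = 2000. The high concentration is a
modeling statement, not a convenience: the emulated phenomenon is a
proliferative fraction that is *stable across samples*, i.e. its
between-sample variation should be small relative to counting noise
(beta SD ≈ 0.009 against a binomial SD of ≈ 0.018 at 500 cells). The
remaining mass is split `dominance_strength : 1 − dominance_strength`
(default 0.85) between the patient's dominant terminal subtype — drawn
once per patient and shared by all its samples — and the other one, which
reproduces the within-patient composition similarity the heterogeneity
analysis tests.

Determinism is structural: every stochastic stage seeds R's RNG from a
(seed, stage-name) substream, so identical configs are bit-identical and
adding a stage never perturbs earlier draws.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: no batch structure beyond library size (the
real analysis would run batch integration first), no doublets, no ambient
RNA, no gradual Prol→Metab/EMT trajectories (labels are categorical), and
marker genes are cleanly program-exclusive. Recovery results on this
cohort are a correctness check of the machinery, not an estimate of
performance on real tumors.

## Problem sizes and runtime choices

The recovery analyses use 10 patients × 2 samples × 300 cells
(6000 cells, 1000 genes) — large enough that the SNN graph, the
downsampled NMF (20 × 50 cells), and the 10-vs-180 distance comparison
all operate in their intended regimes, while a full run stays in tens of
seconds. The unit fixtures are far smaller (≤ 100 genes) so every
brute-force oracle is exhaustive. PCA is computed exactly via the
eigen-decomposition of the HVG covariance matrix (equivalent to full SVD
for the retained components; per-gene z-scores are clipped at ±10 to
bound outlier leverage). Louvain modularity at resolution 1.0 on the
k = 20 SNN graph (Jaccard weights, pruned below 1/15) yields a handful of
subclusters at this scale; on real cohorts the same settings over-segment
into dozens, and the merge stage is what fixes k = 3.

## Known limitations

* QC defaults assume a gene universe of well over 500 genes; toy matrices
  with fewer genes can never pass the feature threshold.
* The exact rank-sum enumeration is O(C(n, n₁)) and is therefore capped at
  pooled size 20; beyond that the normal approximation is used.
* `hcluster_merge` requires at least three subclusters at k = 3; if the
  graph stage returns fewer, raise `cluster_resolution`.
* Concordance's exhaustive matching is capped at six classes per labeling.
* Bulk classification assumes the three groups are separable on the
  100-gene marker space; cohorts without EMT-high samples will fail the
  naming step rather than mislabel.
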