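---
title: "Discovering metabolic meta-programs in single-cell tumour cohorts"
author: "scMMP authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering metabolic meta-programs in single-cell tumour cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Tumours are metabolically heterogeneous at two levels: between patients
(different tumours rely on different metabolic routes) and within a single
tumour (subpopulations of cells coordinately up-regulate different
metabolic modules). `scMMP` implements a pipeline that quantifies both
levels from multi-sample single-cell RNA-seq cohorts. Its centrepiece is
the discovery of *metabolic meta-programs* (MMPs): recurrent intratumour
expression programs over metabolic genes, found independently in many
tumours and summarized by a consensus 30-gene list.

The pipeline covers: quality control and normalization; identification of
malignant cells (a lightweight copy-number smoother plus an iterative
score-based classifier); rank-based gene-set activity scoring for single
cells and pseudo-bulk samples; per-sample NMF with robust-program
filtering and greedy meta-program clustering; abundance and association
statistics; and consensus clustering of cell-type-specific pseudo-bulk
profiles for patient subtyping. A synthetic-cohort generator plants known
cell types, CNV segments and metabolic programs so that every stage can
be validated against ground truth.

## The MMP discovery procedure

Per tumour sample (cells of one cell type, usually malignant cells):

1. **Normalization** — `lognormalize()`: `log(1 + 1e4 * count / total)`.
   The scale factor 1e4 and the natural log are the common single-cell
   toolkit defaults; the upstream method names the normalization function
   but not its parameters.
2. **Gene selection** — `select_metabolic()`: intersect with the curated
   metabolic gene list, keep the top 500 genes by mean normalized
   expression. Ties at the cutoff break lexicographically so runs are
   reproducible.
3. **Scaling** — `scale_and_clip()`: per-gene z-score across cells using
   the population standard deviation (divisor *n*), negatives set to 0.
   Zero-variance genes become all-zero rows.
4. **Factorization** — `nmf_programs()`: one NMF per rank K in 4..9
   (therefore 4+5+...+9 = 39 programs per sample), each factor summarized
   by its 30 largest-coefficient genes. Samples with fewer than 20 cells
   are excluded.
5. **Robust filtering** — `robust_filter()`: a program is kept when it
   (a) shares at least 70% of its genes (21/30, inclusive) with a program
   of a *different* K from the same sample, (b) shares at least 20%
   (6/30, inclusive) with a program from another tumour, and (c) survives
   within-tumour de-duplication: programs are ranked by their maximal
   cross-tumour overlap and any lower-ranked program sharing *more than*
   20% (7/30, strict) of its genes with a kept one is dropped. The
   inclusive/strict distinction preserves the "at least" versus "more
   than" phrasing of the published rules.
6. **Clustering** — `cluster_mmps()`: greedy founder extension. The
   program with the most "similar" other-tumour programs (overlap > 20%)
   founds a cluster; the best-overlapping program is added repeatedly and
   the MMP gene list is recomputed as the 30 genes occurring in most
   members; extension stops when nothing overlaps by more than 20%. New
   founders are attempted while a candidate has at least 5 similar
   programs; clusters with fewer than 10 members are discarded.
7. **Annotation and abundance** — `annotate_mmp()` (hypergeometric
   enrichment against the metabolic universe, BH-adjusted, 0.05) and
   `abundance()` (observed member programs per cancer type versus the
   expectation `N_MMP * N_cancer / N_robust`, abundance
   `log2((obs+1)/(exp+1))`, hypergeometric upper-tail p with Bonferroni
   correction, categories high(-significant)/medium/low/absent evaluated
   in that order).

### Numerical choices in the factorization

The solver minimizes the Frobenius loss with HALS coordinate descent from
a deterministic NNDSVD initialization ('nndsvda' variant: structural
zeros replaced by the matrix mean), at most 500 iterations, relative-loss
tolerance 1e-4 checked every 10 iterations. Multiplicative updates were
tried first and converge too slowly to resolve low-abundance programs
within the iteration budget; HALS reaches cleaner local optima at the
same cost. Because initialization and updates are deterministic, results
are reproducible per (sample, K) without random restarts.

Tie-breaks are fixed everywhere: factor gene lists break coefficient ties
lexicographically; the MMP consensus list breaks occurrence ties by the
summed within-program coefficient rank, then lexicographically; founder
ties go to the earliest sample id, then program id.

## Malignant-cell identification

`infer_cnv_lite()` is a deliberately simple stand-in for HMM-based CNV
callers: reference-subtracted log-normalized expression, averaged in a
101-gene window along each chromosome (truncated at chromosome ends — no
cross-chromosome smoothing), per-cell median-centred and clamped to ±3.
`cnv_score()` is the quadratic sum of the profile. The window size and
clamp are conventions of this implementation; the upstream method names
the tool but not these internals.

`iterative_malignancy()` classifies epithelial cells. Scores are the mean
normalized expression of the top 50 up- and top 50 down-regulated genes
of a signed tumour-vs-normal DE list (the caller provides it;
`tumour_normal_de()` derives one from pseudo-bulk rank-sum tests when no
external bulk DE is available). Cells are split by 2-means in the raw 2-D
score space with initial centroids at the score extremes; each iteration
re-derives DE between the putative groups, rebuilds scores and
re-clusters, until fewer than 0.1% of labels change between rounds
(`stop_rate = 0.001`) or 20 iterations are reached (flagged, not an
error). K-means runs on the *raw* score space: the two axes are on a
common expression scale and their natural spread carries the group
separation; standardizing the axes was found to amplify the noisier
non-malignant axis and destabilize the boundary.

## Scoring

`aucell_score()` ranks genes per cell (descending; ties broken by one
seeded random permutation fixed per run) and computes the area under the
set-recovery curve within the top 5% of ranks, normalized by the best
achievable curve, so scores lie in [0, 1]. The 5% window is the
conventional tool default. `pseudobulk_score()` is a rank-based GSVA-like
stand-in: the standardized difference between the mean rank of set genes
and the overall mean rank, per sample — a signed statistic whose sign and
ordering (not exact values) are the contract.

`differential()` applies Wilcoxon rank-sum tests (normal approximation
with tie and continuity corrections) one group versus the rest, BH
adjustment per contrast, and the published significance gates: |log2FC| >
0.1 (genes) or 0.01 (gene sets), FDR < 0.01, and detection in more than
10% of cells of either population (gene mode only). Fold changes for
sparse data are computed as `log2((mean1 + 1e-9) / (mean2 + 1e-9))` on
the de-logged normalized scale; set-mode means are clamped at zero so the
ratio stays defined for signed score matrices.

## Association screens

`score_correlation()` computes per-tumour Pearson and Spearman
correlations between two score matrices, averages Pearson within a
dataset, tests the per-tumour coefficients against zero with a one-sided
t-test (direction = sign of the mean), BH-adjusts over pairs (Pearson and
Spearman separately), and keeps pairs with both adjusted p < 0.05 and
|mean r| above the use-case threshold (0.4 regulons, 0.1 signatures, 0.3
drug response); `top_k = 3` reproduces the "top three regulators" rule.

`cooccurrence()` computes, per tumour, the fraction of cells with MMP
score above 0.5, z-scales the fractions within dataset, and keeps
positive Pearson correlations with p < 1e-5 as network edges. Raw
AUC-type scores rarely exceed 0.5, so scores are min–max normalized per
MMP within each dataset before thresholding; the original description
does not state the score scale for this cutoff, and this choice is
recorded here rather than asserted as the original authors'.

`pve()` fits `score ~ metric` by least squares and reports the adjusted
R² as the proportion of variance explained with the F-test p-value
(categorical metrics enter as factors).

## Pseudo-bulk subtyping

`build_pseudobulk()` averages log-normalized expression per (sample, cell
type), dropping groups under 20 cells (the same floor as the NMF stage —
the source is silent on a pseudo-bulk-specific threshold).
`consensus_cluster()` resamples 80% of items 1000 times, clusters each
draw by average-linkage hierarchical clustering on the 1 − Pearson
distance, and accumulates co-clustering frequencies; the number of
clusters minimizes the proportion of ambiguous consensus values (PAC, in
(0.1, 0.9) — the original tool asks the analyst to choose k from the
consensus CDFs, PAC automates that choice). The same operation applied to
the transposed pathway × pseudo-bulk score matrix yields correlated
pathway modules; `derive_subtype_signature()` turns cluster labels into
gene signatures via the differential operation.

## The synthetic world

`generate_cohort()` emulates a multi-dataset tumour/normal cohort:

* 2 datasets (one cancer type each), 11 tumour + 2 normal samples per
  dataset, 500 cells per sample;
* 2000 genes on 10 chromosomes plus 13 mitochondrial genes (expected 5%
  of each library), half of the genes flagged metabolic;
* 7 cell lineages with scattered 25-gene marker modules (log2 effect 2).
  Markers are scattered, not contiguous, so lineage identity does not
  mimic a CNV segment under window smoothing. Malignant cells keep the
  epithelial identity and normal epithelium carries an additional
  differentiation module that malignant cells lack — tumours losing
  differentiation programs is what gives the tumour-vs-normal DE a
  genuine down-regulated arm;
* per-tumour CNV segments (120 genes, factors 1.6/0.6) on chromosomes
  that do not carry metabolic genes, multiplying the expression rate of
  malignant cells;
* 15 planted metabolic programs (disjoint 30-gene modules named for the
  canonical processes: DNA synthesis, steroid metabolism, OXPHOS,
  glycolysis, citric-acid cycle, transport, ...), each active in exactly
  12 tumours in a per-tumour fraction drawn uniformly from 0.1–0.3 of
  malignant cells, multiplying module-gene rates by 4 (log2 effect 2);
* counts drawn as negative binomial (shared dispersion 10 — realistic
  overdispersion that exercises the rank-based scoring) with mean =
  log-normal library size (meanlog log 3000, sdlog 0.35; dataset 2
  shifted ×1.2) times softmax-normalized per-cell rates.

Planted module genes are drawn from an upper baseline-expression stratum:
programs are, by construction, modules of *expressed* genes, and this
guarantees they survive the top-500 mean-expression gene selection.

### Why the default cohort has 22 tumours

The within-sample robustness criterion requires a program to be captured
at two different K values. At rank K the factorization can represent at
most K components, so across the K = 4..9 schedule a tumour with *m*
simultaneously active programs can yield at most ~8 robust programs (the
weakest program in a tumour is the one dropped at K = 8 and below). With
15 planted programs each active in 12 tumours, a 20-tumour cohort carries
exactly 9 active programs per tumour — structurally above that ceiling,
so some meta-program would always end below the 10-member floor no matter
how good the solver is. The default cohort therefore uses 22 tumours
(planted load 180/22 ≈ 8.2 per tumour), and active-cell fractions are
drawn per (program, tumour) rather than fixed per program so that no
module is the locally weakest in every tumour it occupies. Both choices
implement the stated calibration goal of the planted catalogue: active
sets are sized so that, post-filter, each meta-program *can* retain its
10 members.

### What the generator does not emulate

No doublets, no ambient RNA, no batch effects beyond dataset-level
library-size shifts, no transcriptional bursting structure, no
gene-length or GC biases, and programs are hard Bernoulli masks rather
than graded activities. A green recovery test therefore establishes that
the pipeline's logic is correct on well-posed input with realistic
overdispersion and sparsity — not that it is robust to every artefact of
real droplet data.

## Degenerate inputs and edge behaviour

Zero-total cells are an error after QC (they cannot arise); zero-variance
genes scale to all-zero rows; zero-variance score vectors drop the
affected tumour from correlation screens with a warning; k-means on
all-identical scores raises a degenerate-input error; non-convergence of
the malignancy loop flags the result instead of raising; empty robust
sets yield empty MMP lists; gene sets without matrix genes score 0 with a
warning.

## Open design points

* The within-sample 70% criterion is read as overlap with *any* other K
  (not every other K).
* The abundance adjusted-p gates only the "high" category, as the
  published rule reads literally.
* The per-library mitochondrial override (up to 40%) is a configuration
  value, not a distribution fit.
* Out-of-date gene symbols are not alias-resolved; set matching is
  case-sensitive on symbols.
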