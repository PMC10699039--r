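---
title: "Profiling checkpoint expression on tumor-infiltrating T cells"
author: "TILprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling checkpoint expression on tumor-infiltrating T cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

TILprofiler analyzes the immune contexture of tumor-infiltrating T cells
from two complementary assays:

* **Flow cytometry**: per-cell fluorescence over five lineage markers
  (CD45, CD3, CD4, CD8, FoxP3) and a ten-checkpoint panel (CD25, CD28,
  CD39, 4-1BB, CTLA-4, ICOS, OX40, PD-1, PD-L1, TIGIT). Supervised
  analysis gates cells hierarchically (CD45+ → CD3+ → CD4/CD8/FoxP3
  splits) and summarizes per-subset checkpoint positivity and mean
  fluorescence intensity (MFI). Unsupervised analysis follows the
  PhenoGraph recipe: auto-logicle transformation, a k-nearest-neighbour
  graph with Jaccard edge weights (k = 30), and Louvain community
  detection.
* **scRNA-seq with paired TCR sequencing**: UMI count matrices per
  patient pass QC, log-normalization, variance-stabilized selection of
  highly variable genes, truncated-SVD reduction with graph clustering
  over a dimensionality/resolution grid, lineage assignment from
  canonical markers, and filtered Wilcoxon differential expression.
  Contig annotations yield patient-scoped clonotypes; cells are
  stratified by TCR clonality (HC: clone of ≥ 3 cells; LC: ≤ 2) and by
  checkpoint expression (HE/LE relative to per-patient medians) into the
  four compartments HC_HE, HC_LE, LC_HE and LC_LE.

The scientific focus is the association the stratification exposes:
clonally expanded CD4+FoxP3+ (regulatory) T cells co-express most
checkpoint proteins, so HC_HE CD4 cells concentrate in the FoxP3+
cluster.

# Key parameters

| Parameter | Default | Units / rationale |
|---|---|---|
| Gating cutoffs | configuration | fluorescence units; manual gates are not estimable from data, a helper places the cutoff at the log-space midpoint of the two log-normal modes |
| Logicle `M` | 4.5 | display decades |
| Logicle `W` | `max(0, (M − log10(T/|r|))/2)` | from the 5th percentile `r` of negative events; 0.5 when no negatives exist |
| PhenoGraph `k` | 30 | nearest neighbours |
| QC | ≥ 5 cells/gene, ≥ 1000 UMI, ≥ 200 genes, ≤ 20% mitochondrial | printed thresholds |
| HVG | 3000 | genes by standardized variance |
| Reduction grid | dims 3–49 step 2; resolution 0.1–1.2 step 0.1 | 24 × 12 combinations |
| DE filters | \|log2FC\| ≥ 0.58 (1.5-fold), pct ≥ 0.25, BH FDR < 0.05 | applied before testing; BH m = tested genes |
| HE rule | ≥ 5 of 10 per-checkpoint indicators | see below |
| Clonality split | HC iff clone size ≥ 3 | size classes 1 / 2 / 3–10 / 11–100 / >100 |

# Design choices in genuinely open places

**Cell-level HE/LE rule.** Medians are defined per patient and per
checkpoint, but a single label per cell is plotted. We form one
indicator per checkpoint (expression strictly above the patient median
for that checkpoint) and call a cell HE when a majority (≥ ceil(P/2),
i.e. 5 of 10) of indicators hold. This respects the per-checkpoint
median definition while yielding one label; an alternative
mean-score-vs-median rule is available (`rule = "meanScore"`). On sparse
data most checkpoint medians are zero, so the indicator effectively
counts detected checkpoints, which is also why the HE fraction is not
pinned at 50%.

**LC/HC differential map.** "Median log2 fold-change" is read as the
median across patients of per-patient log2 fold-changes of group means
(with the +1 pseudocount convention shared with the DE fold-change);
`mode = "log2OfMedianRatio"` provides the other reading.

**Checkpoint burden.** The number of panel genes with a nonzero count;
detection counting matches the magnitude of the reported per-cell
averages (≈ 5–6 of 10 in the FoxP3+ cluster) on sparse data, whereas an
above-median count would halve it by construction.

**Jaccard weights on closed neighbourhoods.** Edge weights compare the
neighbourhoods *including* the cell itself. With open sets, two
coincident cells could never reach weight 1 (each set contains the
other cell but not itself), capping weights at (k−1)/(k+1); closed
neighbourhoods make weight 1 attainable exactly for cells with
identical surroundings.

**Embedding.** The reduction step is a centered, unit-scaled truncated
SVD of the highly variable genes, with optional residualization of
per-cell covariates (e.g. G2M score, mitochondrial fraction) before the
decomposition. The grid search scores each (dims, resolution)
combination by mean silhouette width and by stability (mean adjusted
Rand index against the partitions at neighbouring resolutions) and
chooses the best silhouette subject to a stability floor (default 0.5)
— an automated stand-in for the manual inspection such grids usually
receive.

**Dunn's post-hoc adjustment.** Classical Dunn: each pairwise z-test
p-value is multiplied by the number of comparisons and capped at 1.
The test is named in the sources the package follows; the adjustment is
the classical one associated with that name.

**Mann-Whitney.** Exact enumeration of all group assignments (mid-ranks
for ties) whenever both groups have ≤ 8 observations; otherwise the
normal approximation with tie correction. Kruskal-Wallis on identical
values short-circuits to H = 0, p = 1 (the tie-corrected statistic is
otherwise 0/0).

**Clonotype key.** The strict key — sorted multiset of (chain, V gene,
J gene, CDR3 nucleotide) over the productive contigs of a cell —
compared only within a patient. Alternative keys (`nt`, `aa`,
`beta`) are available; all contigs are kept for cells with more than
two productive chains of a locus.

# The synthetic cohort generator

No public deposition of the original cohorts exists, so validation
relies on a generator that emulates the statistical structure the
analysis assumes, with full ground truth:

* **Flow**: subsets are drawn with the cohort-median proportions
  (CD8 36.5%, CD4+FoxP3− 38.6%, CD4+FoxP3+ 9.5% of T cells, the
  remainder split between DP and DN cells; 20% non-T contaminants so
  gating has something to exclude). Fluorescence is log-normal around
  positive/negative population means (1000/15 a.u., meanlog sd 0.45)
  plus Gaussian background (sd 6), which produces the negative events
  the auto-logicle width estimate needs. Checkpoint positivity per
  subset is strongly Treg-skewed (Treg CD39 0.822); CD25/CD39 rates on
  the CD4 subsets were solved once so that the expected FoxP3+ share of
  CD25+CD39+ CD4 cells is 66.8%:
  with Treg prevalence p among CD4 cells, the share is
  p·a₊b₊ / (p·a₊b₊ + (1−p)·a₋b₋) for positivity rates a, b of the two
  checkpoints.
* **scRNA-seq**: six clusters (three CD8, three CD4, one of them the
  FoxP3+ regulatory cluster) with negative-binomial counts
  (size 1.5, log-normal library factors), canonical marker shifts and a
  15-gene co-regulated module per cluster — single low-abundance
  markers alone would not make clusters separable at ~2,500 UMIs, and
  real transcriptional programs span many genes. The regulatory cluster
  carries a broad 8-of-10 checkpoint program (PD-1 and PD-L1 excluded).
* **TCR**: each cell is productive with probability 0.84; productive
  cells are grouped into clones within their cluster, with clone sizes
  from a zero-truncated geometric law per lineage. The success
  parameters solve 1 − p²(3 − 2p) = f for the cell-level expanded
  fractions f = 0.722 (CD8) and 0.237 (CD4), giving p = 0.3472 and
  p = 0.6836. Cross-cluster clonotype sharing (target 5.4% of
  clonotypes) is planted by swapping single members between same-lineage
  clones of different clusters, which leaves clone sizes and expansion
  rates untouched. Clonotype identifiers are patient-scoped and never
  reused.
* **Planted association**: expanded (≥ 3 cells) FoxP3+ cluster cells
  have their checkpoint-gene means multiplied by 2 (one log2 unit),
  so the HC_HE compartment concentrates in the regulatory cluster and
  the burden shift between HC and LC Tregs lands near one checkpoint.

What the generator does **not** emulate: doublets, ambient RNA,
empty droplets, batch effects, read-level noise, V(D)J biology beyond
identity/productivity, or any association between clone size and
library depth. Passing recovery tests therefore demonstrates that the
pipeline measures what it claims on data satisfying its assumptions,
not that those assumptions hold in any particular tumor.

# Numerical choices

* The logicle forward transform inverts the biexponential by 60-step
  vectorized bisection (display precision far below 1e-10); the d
  coefficient solves 2·ln(b/d) = w(b+d) by Brent's method, with d → b
  as the linear width vanishes.
* kNN search is exact blockwise Euclidean; ties break by cell index
  after a stable sort so runs are deterministic.
* Louvain randomization is confined to the node visiting order drawn
  from the seeded RNG; identical seeds give identical partitions.
* HVG standardized variance clips standardized values at sqrt(n cells)
  and uses a loess fit (span 0.3) of log10 variance on log10 mean.
* Degenerate cases: min = max marker profiles normalize to 0; a single
  cluster has silhouette −1; clusters missing one clonality class skip
  their test but keep their means; patients without clonotyped cells
  are omitted from medians.

# Problem sizes

Tests and the acceptance script run the generator at desk scale — flow
samples of 10,000 cells, single-cell cohorts of 5 patients × 2,000
cells, clustering grids restricted to a handful of dimensionalities and
resolutions — sizes chosen so the full validation cycle completes in
minutes while keeping every recovery check well-powered. The full
default grids (3–49 × 0.1–1.2) remain the package defaults for real
analyses.

# Known limitations

* Gating thresholds are configuration, not estimated from controls;
  compensation, spillover and viability modeling are out of scope, as
  is FCS parsing (input is CSV per sample).
* Multi-patient runs concatenate without batch correction; per-patient
  analysis is the intended default.
* The embedding is a linear SVD, not a count-model factorization; with
  covariate residualization it is a pragmatic replacement whose
  substitution is visible in reports.
* UMAP is delegated to uwot when installed and is used for display
  only.
* The compartment analysis conditions on the clustering; uncertainty in
  cluster assignment is not propagated.
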