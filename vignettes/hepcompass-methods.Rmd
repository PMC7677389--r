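---
title: "Quantifying hepatocyte functional compensation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hepatocyte functional compensation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hepcompass analyzes how hepatocytes reorganize their zone-specific gene
expression after acute liver injury. Two injury settings motivate the
design: toxic pericentral injury (acetaminophen overdose, which kills the
hepatocyte layers around the central vein) and surgical resection (partial
hepatectomy, which removes a large fraction of liver mass without zonal
selectivity). The package quantifies three phenomena from single-cell
RNA-seq and smFISH data: the loss and compensatory re-establishment of
zonated expression programs, the injury-scaled upregulation of core liver
function genes, and the division of labor between cycling and non-cycling
hepatocytes.

This vignette documents the models, the numerical choices, and what the
synthetic-data validation does and does not establish.

## Normalization and quality control

Barcodes with fewer than `min_genes` detected genes (default 400 for
genome-wide data) are discarded as non-cells. Counts are library-size
normalized to a fixed scale (10,000) and natural-log transformed:
`value = ln(1 + 1e4 * count / total)`. Zeros stay zero, so sparsity is
preserved. The natural log follows the convention of the standard
single-cell toolchains; the base is not scientifically material because all
downstream statistics are rank- or difference-based within one
transformation.

Cells are additionally screened on a fixed hepatocyte signature (twelve
highly expressed genes spanning the lobule: Apoa1, Glul, Acly, Asl, Cyp2e1,
Cyp2f2, Ass1, Alb, Mup3, Pck1, G6pc, Fabp1). Cells scoring more than 3
standard deviations below the mean are removed as non-hepatocytes. When the
score is constant the filter removes nothing and warns, since a degenerate
score carries no outlier information.

PCA is computed on per-gene standardized values with no variable-gene
selection (the simplest defensible choice; both are exposed as
configuration). Component signs are fixed by making each component's
largest-magnitude loading positive, and per-component variance fractions
are reported against the total across all components.

## Module scores with bin-matched controls

A module score compares a gene program's mean expression in each cell with
the mean of control genes matched on overall expression. All genes are
sorted into 25 quantile bins (equal gene counts) by mean normalized
expression; each program gene contributes 100 control draws from its bin,
excluding program genes, with replacement when the bin is smaller. The
score is `mean(program) - mean(pooled controls)`. Subtracting bin-matched
controls removes the component of the program mean explained by expression
level alone, so scores are comparable across cells with different depths.

Two degenerate situations are handled explicitly: program genes absent from
the matrix are dropped with a warning (at least one must remain), and a bin
consisting entirely of program genes falls back to excluding only the
scored gene (with a warning) so the score stays defined.

## Deriving zonal signatures from an anchor gene

Pericentral and periportal signatures are derived from a gene-by-gene
Pearson correlation screen against Cyp2e1, the canonical pericentral
anchor. Genes with `r > 0.3` seed the pericentral list and genes with
`r < -0.3` the periportal list; the screen also reports the mean and
mean ± 3 SD of the full correlation distribution so the cutoff can be
checked against it. Both lists are then restricted to moderately expressed,
variable genes. "Moderately expressed with large variability" is made
concrete as three quantile filters, all configurable: detected in at least
5% of cells, mean expression at or above the 40th percentile of gene means,
and variance/mean dispersion at or above its median. Pearson (not Spearman)
correlation is the default because the screen's summary statistics are
moments of raw correlations; the method is switchable.

The composite zonation score is the periportal minus the pericentral module
score, one axis on which pericentral hepatocytes score negatively. An
alternative construction from a published zonation table keeps non-randomly
zonated genes (q < 0.01) that are at least averagely expressed in the
scored dataset and assigns each to the lobule half holding more of its
layer-profile mass; exact half-mass ties are dropped.

The percent-positive statistic uses one pooled threshold per gene — the
mean normalized expression over all cells of all conditions — and counts
cells strictly above it, per condition. A single global threshold is what
makes the per-condition percentages comparable.

## Differential expression and pooling

Between two cell groups, genes are tested only when detected in at least
10% of either group and when the average log fold-change magnitude reaches
0.25, where `avg_logFC = ln(mean_a(exp(x)-1)+1) - ln(mean_b(exp(x)-1)+1)`
on normalized values (the expression-scale construction used by the
standard toolchain, so the printed thresholds keep their usual meaning).
Two-sided p-values come from exact enumeration of all group-label
assignments when both groups have at most 8 cells (ties are handled because
the observed ranks themselves are permuted), otherwise from the normal
approximation with tie and continuity correction. Adjustment is Bonferroni
over all genes in the matrix, not only the tested ones.

Per-injury-model results are pooled across time points as the union of
significant genes (`p_adj < 0.05` by default). A gene significant at
several time points keeps its record of largest |avg_logFC| — so a gene up
early and down late is retained once, in the direction of its strongest
change — and exact magnitude ties fall to the earliest time point, which
makes pooling deterministic and order-independent given chronologically
ordered inputs. Cohen's d uses the pooled n−1-weighted standard deviation
with star annotations at |d| > 0.2, 0.5, 0.8.

## Gene-set analysis

The set statistic is Fisher's combination, `-2 * sum(ln p)`, over the
unadjusted gene-level p-values of the set's tested genes. Genes filtered
out before testing enter the universe with p = 1: they carry no evidence,
and a fully defined universe is what makes gene sampling meaningful.
Significance is empirical: random gene subsets of the same size are drawn
without replacement from the universe and the p-value is
`(1 + #(perm >= obs)) / (n_perm + 1)`, so it can never be zero and makes no
independence assumption across genes. p-values are floored at 1e-300 before
logs. Benjamini–Hochberg q-values are computed per injury model; a set is
shared when `q < 0.05` in both models and unique to one model when
significant there and showing no trend (`q >= 0.2`) in the other. The
statistic is non-directional.

## Spatial smFISH quantification

Spot radii are Euclidean distances to the nearest point of the vein polygon
boundary — not to its centroid, so the measure is shape-independent — and
spots inside the lumen are excluded and counted separately. Concentric
rings of width 30 μm (one hepatocyte diameter; configurable) cover
distances up to the farthest in-image point, and each ring's count is
renormalized by the ring area contained within the image. That area is
computed exactly: the ring region is the difference of two outward
Minkowski offsets of the vein polygon (edges plus corner arcs polygonalised
at an angular step of 2π/20000, giving relative area errors below 1e-7),
clipped to the image rectangle by Sutherland–Hodgman. The construction
requires a convex vein polygon, which covers the manually outlined, roughly
circular veins this analysis is designed for; non-convex veins are
rejected rather than silently mis-measured. Necrotic acellular regions are
not subtracted from ring areas by default.

The reported AUC ("average total RNA counts") is the trapezoidal integral
of density over ring midpoints. The zonation boundary is the smallest
radius at which the cumulative density mass over radius — per-ring density
integrated over ring width, linear within a ring — reaches 90% of its
total. The step-cumulative (rather than a midpoint-trapezoid cumulative) is
the construction under which all mass in the first ring yields a boundary
inside the first ring, and a constant density yields a boundary at 90% of
the populated span. Boundary shifts between conditions subtract the
untreated boundary and are antisymmetric by construction.

Spot-to-cell assignment uses even-odd point-in-polygon tests; a spot
strictly inside two outlines indicates overlapping segmentation and raises
an error, while a sub-micrometre boundary tie goes to the lowest cell id
and is counted. Macrophage proximity profiles bin every non-macrophage
cell by centroid distance to the nearest macrophage (bins of 30 μm, one
cell diameter) and report mean per-cell counts. Histogram comparisons use
the two-sample Kolmogorov–Smirnov test.

## The synthetic lobule generator

The generator is first-class, tested code: it produces count matrices and
smFISH geometries with planted ground truth so that every estimator in the
package can be checked for parameter recovery.

Expression model: nine lobule layers (layer 1 pericentral). Zonated genes
follow exponential layer profiles `exp(±slope * layer)` with per-gene
slopes drawn from 0.15–0.4, i.e. roughly 3- to 25-fold
pericentral-to-periportal ratios, the range typical of reference zonation
profiles; a degenerate slope range plants slope-matched genes for
correlation-screen validation. Baseline abundances are heterogeneous
(log-normal, sd 1.1 across genes, matching the decades-wide spread of real
transcript abundances), with zonated genes drawn from the upper half as the
canonical zonation markers are highly expressed. Counts are negative
binomial with shared size 4 (squared coefficient of variation 0.25 beyond
Poisson, typical of per-gene fits) on a log-normal library size, with a
small independent extra-zero rate (1%; sampling zeros already dominate in
this regime). Gene classes: pericentral, periportal, housekeeping ("flat"),
liver-function, cell-cycle, and stress-response genes, with real marker
symbols heading each class so the fixed signatures intersect the matrix.

Injury is encoded per condition by four recoverable parameters: pericentral
layer loss (necrosis removes the first k layers), outward shift of the
pericentral program by Δ layers (`profile(max(1, l - Δ))`, the
"compensation" phenotype), a multiplier f ≥ 1 on function and stress genes
(functional upregulation scaled by injury extent), and a cycling
subpopulation (fraction p, cell-cycle genes boosted, the differentiated
hepatocyte program — zonated, function, and stress genes, but not
housekeeping — scaled by δ ≤ 1). The shipped conditions are UT (no injury),
A6 (k = 2, f = 1.5, 1% cycling), A24 (k = 2, Δ = 2, f = 2, 5% cycling,
δ = 0.7) and P3 (Δ = 1, f = 3, 1% cycling), reflecting pericentral necrosis
by 6 h, midzonal compensation with the proliferative peak around 24 h, and
the larger functional demand after resection (~70% mass loss) than after
toxic injury (~10%).

Spatial model: cells sit on concentric rings between the vein and the
lobule edge at one-cell-diameter (30 μm) spacing with alternate-ring phase
shifts and a small positional jitter (±0.12 diameters). The jitter matters:
real tissue is not a lattice, and without it no two centroids fall within
one cell diameter, which would make the first macrophage-proximity bin
structurally empty. Outlines are hexagons of radius 0.32 diameters so
jittered cells can never overlap. Per-cell spot counts are Poisson with
mean given by a radial profile of distance to the vein edge, boosted within
30 μm of a macrophage when macrophages are planted; spots scatter uniformly
inside the outline. The planted 90%-mass radius of each gene is computed
from the noise-free profile λ(d) directly (not weighted by circumference),
because areal cell packing is uniform and the analysis estimates the
density curve, whose expectation is proportional to λ.

What the synthetic validation shows — and does not. Passing recovery tests
establishes that the estimators are implemented correctly and are
statistically calibrated under a generative model with the assumed
structure: monotone exponential zonation, shared NB dispersion, independent
extra zeros, condition-independent library sizes, circular vein geometry.
Real tissue violates several of these (non-monotone profiles, correlated
gene modules, segmentation errors, irregular veins, ambient RNA), so green
tests do not certify accuracy on real data; they certify the machinery.

## Numerical and reproducibility choices

All randomness is locally seeded: every stochastic operation takes an
explicit seed, uses R's Mersenne–Twister via a scope that saves and
restores the global RNG state, and the pipeline derives per-step sub-seeds
from a master seed and the step name (a 31-ary string hash modulo
2^31 - 1). Standard deviations use the n−1 denominator throughout. Ties:
quantile bins break mean-expression ties by stable order; pooling ties fall
to the earliest time point; boundary ties in spot assignment go to the
lowest cell id. Degenerate inputs (constant scores, empty bins, zero-area
rings with spots, zero-total cells) raise errors or warn-and-pass as
documented on each function rather than producing silent numbers.

Problem sizes in the shipped tests and the acceptance script are chosen so
the whole validation runs on a laptop in minutes: matrices of a few hundred
genes by a few hundred to a few thousand cells, ten replicate seeds per
recovery claim, 500 replicates for calibration checks, and 10^5–10^6 draws
for tail and Monte-Carlo geometry checks.

## Known limitations

The ring-area computation requires a convex vein polygon. The gene-set
statistic is non-directional. The generator does not simulate ambient RNA,
doublets, immune-cell transcriptomes, or 3-D tissue; condition labels are
taken as given and no clustering is performed. The exact cell-cycle marker
list is replaceable data (a GMT), not a modeling commitment.
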