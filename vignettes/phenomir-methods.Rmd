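---
title: "Methods: simulating and analysing a miRNA high-content screen"
author: "phenomir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a miRNA high-content screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomir)
```

# The assay being modelled

phenomir re-implements, as a tested pipeline, the analysis of an arrayed
microRNA-mimic gain-of-function screen in human pluripotent cells read out
by automated fluorescence microscopy. Cells in 96-well plates are
transfected with one mimic per well (triplicate wells per mimic), stained
for the pluripotency factor OCT4 (green channel) and the G2/M marker
Cyclin B1 (CCNB1, red channel), and counterstained so that the blue
channel carries both a bright nuclear dye and a dimmer whole-cell dye.
That staining design means both compartments can be segmented from the
blue channel alone: nuclei are the *high*-intensity class and cytoplasm
the *medium*-intensity class. Each well is imaged at 9 sites; each screen
carries a negative-control mimic with no human targets (`miR-Ctr`), two
differentiation controls (`atRA`, `esiRNA-OCT4`) and a lethal transfection
control (`siRNA-UBC`).

Because no raw screen images are publicly deposited, the package ships a
first-class synthetic-screen generator whose defaults encode these assay
conditions; every downstream stage is exercised against the generator's
ground truth.

# The synthetic-screen generator

`screen_layout()` places treatments on plates: every mimic's replicate
wells sit on a single plate and every control appears on every plate, so
per-plate normalization and QC are always defined. 31 mimics in
triplicate plus controls occupy two 96-well plates, as in the assay the
generator emulates.

`sample_cells()` draws per-field ground truth. Cells are concentric
ellipse pairs (nucleus strictly inside the cell, shared orientation), the
minimal shape family that exposes every measured feature; nuclear
boundary irregularity is a low-order radial perturbation
(`r(theta) = r0 (1 + a cos(3 theta + phi))`), which makes sub-unit
solidity reachable. Distributions and defaults:

* cell count per field: Poisson, mean 100 x the treatment's count
  multiplier. 100 cells per 512 x 512 field at ~0.65 um/px is a typical
  sub-confluent density for a 10x objective; the source assay reports no
  pixel geometry, so these are package choices, not inferred values.
* nucleus radius 8 px and cell radius 14 px (lognormal, sdlog 0.15 and
  0.12, arithmetic means fixed at the stated values); elongation (axis
  ratio) lognormal around 1.3; irregularity amplitude lognormal around
  0.2 (capped at 0.35). Marker levels are lognormal (sdlog 0.25) around
  OCT4 6000/2000 and CCNB1 3500/2500 arbitrary 16-bit units in
  nucleus/cytoplasm.
* a per-field size factor and intensity factor (lognormal, unit mean,
  `field_cv = 0.02`) emulate field-to-field heterogeneity in plating,
  staining and focus. Without it, tightly-distributed discrete features
  (notably the quantized perimeter estimator) collapse to a single median
  across all sites, which no real screen does.
* placement is rejection sampling with a minimum centre distance of 0.9 x
  the summed outer radii, up to 200 retries; cells placed past the cap
  are kept but flagged `overlap`.
* effect profiles are multipliers on the negative-control baseline.
  Built-ins: the lethal control keeps 10% of cells (so the
  transfection-efficiency QC reads ~0.9 against its 0.85 threshold) and
  the differentiation controls halve all four marker levels.

`render_field()` paints the blue plane as background (300), cell body
(3000) and nucleus (12000); green and red planes carry each cell's true
compartment levels. With noise enabled the planes are Gaussian-smoothed
(sigma 1 px, a minimal PSF stand-in), given Poisson shot noise plus
additive Gaussian read noise (sd 50), clipped to [0, 65535] and
quantized - the standard fluorescence noise model. With `noise = FALSE`
the painted planes are only quantized, which the fixture tests rely on
(exactly three blue classes; compartment medians equal to painted
levels).

What the generator deliberately does **not** model: realistic optics
(PSF shape, vignetting, illumination gradients), colony-level morphology,
cell-cycle structure, segmentation-adversarial textures. Tests passing on
synthetic screens therefore validate the *analysis arithmetic and its
recovery behaviour*, not segmentation robustness on real micrographs.

# Segmentation

`segment_nuclei()` smooths (sigma 2 px), applies three-class automatic
thresholding - a two-threshold generalization of Otsu's method maximizing
between-class variance on a 256-bin histogram - and takes the top class
as the nucleus mask. Holes are filled, touching nuclei are split by a
watershed on the distance transform (EBImage), and objects outside
[30, 5000] px^2 or touching the border are removed. Truncated border
objects would bias morphometrics, hence the default exclusion.

Two numerical guards matter. A constant field has no three-class
structure and returns an empty mask rather than an error. A blank,
noise-only field *does* have an Otsu split, so the segmenter additionally
requires the top and bottom class means to differ by at least
`min_contrast` (500 intensity units, against a nucleus/background
separation of ~11700 at defaults); below that the field is declared
empty. The splitting controls are EBImage's `tolerance` (minimum depth
between seeds) and `ext` (local-maximum neighbourhood radius), the same
pair of knobs as a minimum seed distance.

`segment_cells()` takes the union of the middle and top classes as the
cell mask and assigns pixels to nuclei by seeded propagation constrained
to the mask (the CellProfiler-style secondary-object step). Mask regions
unreachable from any nucleus are discarded; nucleus pixels are forced
into their own cell, so nucleus-within-cell containment holds by
construction. `derive_cytoplasm()` is the per-label set difference;
empty cytoplasm is allowed and flagged, and a nucleus pixel outside its
cell is a hard error.

Coordinates follow R's 1-based matrix convention; areas are px^2.

# Per-cell features

For each cell: areas (pixel counts), perimeters, solidity and
eccentricity of both compartments, and *median* (not mean) marker
intensities over nucleus and cytoplasm pixels - medians because that is
the robust per-cell summary the profiled assay reports. The perimeter is
the Cauchy-Crofton estimator, pi/4 times the number of exposed pixel
edges (4-neighbourhood plus image border); it is unbiased for smooth
convex shapes (a digital disk of radius r exposes ~8r edges, giving
~2 pi r) and its constant is recorded here because estimator choice
shifts absolute perimeter values. Solidity divides the pixel count by
the convex-hull area expressed in equivalent lattice pixels (Pick's
theorem: interior + boundary lattice points = A + B/2 + 1), clamped to
[0, 1]; this makes a digitized convex shape score 1 instead of slightly
above. Eccentricity comes from the second central moments with the
1/12-per-pixel term, `e = sqrt(1 - lmin/lmax)`.

The profiled feature panel lists "solidity" and "eccentricity" without a
compartment. The package computes both compartments and defaults to
*cell* solidity and *nucleus* eccentricity: shape reentrances develop in
the spread cell body upon differentiation, whereas elongation is most
interpretable for the nucleus. Both choices are configurable
(`build_profile(features = ...)`).

# Normalization and the phenotypic profile

Aggregation is fixed as: per-site median over cells, then
percentage-of-control (POC) per plate and feature
(`100 x value / median of the negative-control sites on the same
plate`), then the per-treatment median over the 27 site values (3 wells
x 9 sites). The source analysis states the 27 values and the final
median but not the intermediate reference level; site-level control
medians were chosen for robustness, and the order is a pure function of
the inputs (site order never matters). Cell counts are normalized with
the same POC formula on site counts. Sites with zero cells keep count 0
but contribute no morphology values - missing morphology is not zero
morphology.

QC: transfection efficiency is `1 - median(lethal site counts) /
median(negative-control site counts)` per plate (pass at >= 0.85), and
OCT4 knockdown for each differentiation control is `1 - POC/100` of its
wells' OCT4-nuclear medians.

# Clustering

Treatments and features are clustered with average linkage (UPGMA) under
the centered-correlation distance `1 - Pearson(r)` (the uncentered,
cosine form is available behind a flag for fidelity experiments).
`stats::hclust` provides the agglomeration; an independent naive O(n^3)
UPGMA implementation lives in the test suite and the two agree to 1e-10
on random matrices. Zero-variance vectors make the metric undefined and
are a hard error - the generator's field-level variability exists partly
so that no honest profile column is degenerate. Profiles are clustered
as raw POC values (no rescaling): the distance is already invariant to
per-row affine transforms, which the tests verify.

Named cuts mirror screen nomenclature: the top-level k-cut is lettered
A, B, ... in dendrogram order, a sub-cut of B gives B.1/B.2, and a
further cut gives B.2a/B.2b. Cut depths are an explicit user
specification (default top-level k = 2) - the published sub-cluster
boundaries were visual choices that cannot be derived algorithmically.
`export_treeview()` writes Cluster 3.0-compatible `.cdt`/`.gtr`/`.atr`
files (node correlation column = 1 - merge height) plus a
yellow-above/blue-below-control PNG heatmap.

# Targets, enrichment, Venn arithmetic

`read_targetscan()` consumes a TargetScan-style tab-delimited table
(family, mature member name, gene symbol, species), filters to human
(9606) and resolves a queried mature miR first by exact name and then
through its seed family parsed from the slash-separated family string -
mirroring how TargetScan publishes family-level predictions.
`shared_targets()` defaults to the strict intersection over a cluster's
members ("commonly targeted" read as *all* members; a majority rule is
available via `min_fraction`).

Enrichment is a documented stand-in for the DAVID web tool, which is
version-pinned and not reproducible offline: upper-tail hypergeometric
`P(X >= k)` per gene set with BH FDR across the collection, plus DAVID's
conservative EASE variant (one overlap gene removed). The default
universe is the collection's own membership; configurable, since the
original background is unstated. `compare_pathway_sets()` computes every
region of a 2-4 set Venn with counts and one-decimal percentages of the
union - the arithmetic used to compare per-subcluster pathway lists.
`read_pathway_workbook()` ingests such lists from an Excel workbook when
one is available.

# qPCR and group statistics

`ddct_fold()` implements 2^-ddCt with the *arithmetic* mean of control
dCt as the reference (matching "mean expression level of control
transfected cells"); geometric centering was considered and rejected for
fidelity. Folds are invariant to any global Ct shift.

`mann_whitney()` is one-tailed by explicit caller choice (no automatic
direction detection - that invites silent p-hacking). For combined
n <= 12 the p-value is exact, enumerating all C(m+n, m) group
assignments over the observed data with mid-ranks, which remains valid
under ties; larger samples use the tie-corrected normal approximation
with continuity correction. `kruskal_wallis()` delegates to
`stats::kruskal.test` (tie-corrected H, chi-square reference).
`dunn_test()` implements the rank-mean z with tie correction and a
Bonferroni-style family adjustment - the correction assumed for
Prism-style "Dunn's multiple comparison"; Holm is available behind a
flag.

# Problem sizes used in the checks

The reference recovery experiment (`two_group_screen_config()`) plants
12 mimics - six with OCT4/CCNB1 multipliers 1.4-1.6 (two exactly at 1.5)
and six with 0.5-0.7 - in triplicate at 9 sites/well with ~100 cells per
512 x 512 field, i.e. 432 rendered and segmented fields per run; the
package processes fields streamingly so memory stays flat. Oracle checks
use 200 random matrices (n <= 7) for UPGMA, exhaustive enumeration for
hypergeometric cases up to N = 25, and 10,000 simulated null trials for
the Mann-Whitney type-I level.

# Known limitations

* Equivalence with the original CellProfiler module chain cannot be
  verified - the published analysis names no algorithms or thresholds -
  only emulated with the standard pair (multi-level Otsu; distance-
  transform watershed + seeded propagation).
* The DAVID pathway lists themselves are database-version-dependent and
  are consumed as inputs, not recomputed.
* The generator's simplifications above mean real-image performance is
  out of scope; the segmentation accuracy figures quoted by the tests
  (count error <= 5%, IoU >= 0.8) are properties of the synthetic
  conditions.
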