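---
title: "Methods: screening readouts, normalization and hit calling in cftrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening readouts, normalization and hit calling in cftrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cftrscreen)
```

# The scientific problem

F508del, the most common cystic-fibrosis mutation, destabilizes CFTR so
severely that most of the protein is degraded before it can fold; corrector
drugs act on the immature, ER-resident glycoform (Band B), so screens that
aim to enlarge that repairable pool need readouts of *protein amount and
localization*, not channel function. `cftrscreen` implements the two such
readouts used in automated corrector screening — per-cell immunofluorescence
quantification from high-content microscopy, and plate-reader fluorescence
normalized for cell number — together with the screen-level statistics that
decide whether an assay is usable (Z factor) and which compounds are hits
(the 3-SD rule).

# Imaging arm

## Segmentation model

Each field carries two channels: a DNA stain with high-contrast nuclei and
low-contrast cytoplasmic staining, and the target immunofluorescence. The
pipeline assumes (i) nuclei are the brightest objects in the nuclear
channel, so a single intensity threshold isolates them; (ii) every cell
contains exactly one detected nucleus; (iii) cytoplasmic staining, though
dim, is above background, so a second, lower threshold outlines cell extent.

* `segment_nuclei()` thresholds the nuclear channel (pixels `>= threshold`
  are foreground), labels connected components (4-connectivity, via
  `EBImage::bwlabel`), and discards components below `min_nucleus_area`
  (default 10 px) as noise specks. `"auto"` uses Otsu's method on the
  channel histogram — the protocol this emulates names only "intensity
  threshold", and Otsu is the standard parameter-free default; a fixed
  numeric override keeps runs exactly reproducible across exposure changes.
* `segment_cells()` forms the cytoplasmic foreground (pixels at or above
  `cyto_threshold`, plus all nucleus pixels) and partitions it among the
  nucleus seeds by geodesic nearest-seed assignment: a pixel joins the
  nucleus it can reach by the fewest 8-neighbour steps *within the
  foreground*. Distance ties go to the lower label — an explicit, arbitrary
  but deterministic rule. Foreground with no reachable nucleus stays
  background and is counted. The `"auto"` cytoplasm threshold applies Otsu
  to the pixels outside nuclei, i.e. to the background/cytoplasm mixture,
  because a whole-histogram Otsu on a trimodal image tends to land between
  cytoplasm and nuclei instead.

## Ring ROIs

Ring widths are measured in the Chebyshev metric: "a 2 pixel wide band"
means two erosion/dilation steps with a 3×3 structuring element, matching
the pixel-step phrasing used for such ROIs. Positions beyond the field
border count as background, so a cell at the edge still has a margin band
there (those cells are excluded from measurement anyway, see below).

* Plasma-membrane ROI (`derive_pm_roi`, width 2): the cell's pixels whose
  Chebyshev distance to the nearest non-cell pixel is at most the width.
  Pixels of *other* cells count as non-cell, so two near-touching cells
  both keep margin bands.
* Perinuclear ROI (`derive_perinuclear_roi`, width 5): pixels inside the
  cell, outside its nucleus, within the width of the nuclear mask — an ER
  proxy. The ring is clipped by the cell mask.

In small cells the two rings can overlap. Nothing in the protocol says
whether the original analysis prevented that, so the package computes both
independently and reports the overlap area per cell
(`overlap_pm_perinuclear`) rather than guessing an exclusion rule.

The implementation iterates a 3×3 erosion/dilation kernel; the test suite
verifies it pixel-for-pixel against brute-force distance computations
(one-shot `(2w+1)²` neighbourhood scans, plus fully per-pixel loops on small
masks) over hundreds of random blob masks.

## Measurement and pooling

`measure_cells()` reports, per cell, the arithmetic mean of the target
channel over each ROI, with pixel areas. Two deliberate choices:

* Cells touching the field border are excluded and counted: their PM ring is
  truncated by the image edge, which would bias the margin mean. This is
  standard high-content practice.
* An empty compartment (e.g. a nucleus filling its whole cell leaves no
  perinuclear ring) yields a *missing* mean, never 0; missing values are
  excluded from well pooling so they cannot drag well means toward zero.

`summarize_well()` pools all cells across a well's fields with equal weight
— a mean of cell-level means, not a mean of field means — because each
readout is defined as the mean fluorescence over all cells imaged in the
well's nine fields. With cell means {100} in one field and {200, 200} in
another, the well mean is 166.67, not 175.

"Total" fluorescence is reported as the mean over the whole cell mask,
following the protocol's wording ("mean fluorescent intensity"); the
integrated sum is kept as an auxiliary column (`integrated_total`) for users
who prefer total mass.

# Plate arm

Each plate carries an immunostain read and a viability read, plus a layout
assigning wells to roles: DMSO cell controls (baseline), ALLN positive
controls (proteasome inhibition, maximal immunostain), Hyamine viability
controls (killed wells, zero-viability anchor), and test compounds. The
three normalizations are applied with same-plate control medians:

* `fold_increase = value / median(cell controls)`;
* `% viability = 100 * (value − median Hyamine) / (median cell control −
  median Hyamine)` — values below the Hyamine median go negative and are
  reported, not clipped;
* `normalized fold increase = fold increase / fractional viability`.

Numerical choices: medians use R's standard midpoint rule for even counts
(no tie rule is printed in the protocol); missing well values are carried as
`NA`, never 0, and wells missing a read are excluded from control medians;
the normalized fold increase is flagged missing when fractional viability is
at or below a configurable floor (default 0.1), because dividing by
near-zero viability amplifies dead-well noise without bound — the unguarded
ratio is retained in `normalized_fold_increase_raw` so nothing is hidden.
The division uses *fractional* viability (the unscaled form of the printed
formula); percent viability is reported alongside.

`final_concentration()` implements the dilution bookkeeping of the two
protocols: a 10 mM stock diluted 500-fold and added in equal volume gives a
10 µM final screening concentration; 5 µl of a 150 µM working solution into
25 µl gives 25 µM.

# Screen statistics

* **Z factor** (`z_factor`): the screening-window coefficient
  `1 − 3(σ₊ + σ₋)/|μ₊ − μ₋|` with sample SDs, computed per plate from
  designated control well sets and aggregated as mean ± SEM
  (`aggregate_z`), mirroring how such screens report assay robustness.
  Zero-variance separated controls give exactly z = 1, the perfect-assay
  limit; equal control means are an error (undefined separation), reported
  per plate in the screen report rather than aborting the screen. The
  statistic is invariant under joint affine transforms of both arms. Which
  well sets play positive/negative is configuration — an imaging screen may
  contrast mutant- vs wild-type-expressing wells, a plate screen its
  in-plate controls.
* **Hit calling** (`call_hits`): mean and sample SD are computed over the
  test-compound population (controls excluded), and a compound is a hit when
  its value is *strictly* greater than mean + k·SD, k = 3 by default. Ties
  at the threshold are non-hits. No multiple-testing correction is applied:
  the 3-SD rule *is* the selection rule being implemented; under a Gaussian
  null it admits ~0.135% of compounds, which the tests verify within the
  binomial 99% band at n = 10,000. Sample SD (n − 1) is used throughout the
  package.

# Synthetic-data generators

No screening dataset is deposited with the protocol this package
implements, so both input kinds are emulated with known ground truth.

**Fields** (`simulate_field`): cells are concentric regions — a nuclear
disk, a perinuclear band, cytoplasm, and a PM band — painted at fixed
intensities with additive Gaussian noise (clipped at zero) on the target
channel. The compartment geometry is built with the same Chebyshev ring
definitions the analysis uses, so noiseless recovery tests are exact rather
than approximate; ground-truth means are computed from the painted image, so
they remain correct even when a small geometry makes rings overlap. Cells
are placed by dart throwing on integer centers, at least `2·cell_radius + 2`
apart and clear of the border; placement failure is an error naming the
constraint — cells are never silently dropped. One seed governs everything,
split by a fixed rule (placement uses `seed`, pixel noise `seed + 500009`,
field *i* of a well `seed + i`), so ground truth never changes when only the
noise level does. Default geometry (nucleus radius 4 px, cell radius 14 px)
keeps the 5-px perinuclear band clear of the 2-px PM band, so every painted
compartment mean equals its nominal intensity; default intensities put
nuclei far above cytoplasmic staining, as with a DNA stain imaged at 20×.

The generator deliberately omits optics: no point-spread function,
vignetting, illumination gradients, autofluorescence, cell-shape variation
or touching cells. Passing recovery tests therefore demonstrates that the
*measurement and bookkeeping* are correct, not that segmentation is robust
to real microscopy artifacts — threshold segmentation on real fields
inherits all the usual caveats.

**Plates** (`simulate_plate`): each well's value is drawn as
`mean × (1 + cv·Z)`, clipped at zero, with the mean set by the well's role
and `cv = 0` the exact noiseless limit. Spiked hits multiply the immunostain
mean of their test wells. Defaults were chosen once to resemble a robust
corrector screen: the positive control at 3× the cell-control immunostain
with cv = 0.07 yields plate Z factors around 0.55–0.65, the window reported
for screens of this design, and the viability read centers living wells at
4 × 10⁶ AFU — the plate-development level at which such assays stop the
alamarBlue incubation — with killed wells far below. A multiplicative
(constant-CV) Gaussian model is the simplest that exposes threshold
behaviour; Poisson photon statistics and spatial plate effects
(edge/gradient artifacts) are out of scope, so the simulated screens cannot
probe normalizations against those.

# Pipeline, configuration and problem sizes

`load_config()` reads a single YAML file over explicit defaults (PM width
2 px, perinuclear width 5 px, nine fields per well, k = 3, viability floor
0.1); unknown keys are an error listing each offending name, so typos never
silently become defaults. `run_pipeline()` chains simulation → scoring →
report deterministically from one seed (plate *p* uses `seed + p − 1`) and
writes all intermediate tables, the report directory, and a manifest
recording the package version, a hash of the configuration (excluding
output paths), and the seed — enough to reproduce a run exactly.

The test suite and acceptance script run on sizes chosen to exercise every
code path while staying desk-scale: fields up to 256² px with up to 50
cells, ring-oracle checks on ≥100 random blobs up to 64², hit-recovery
over 100 simulated 384-well screens (cv = 5%, four 3× hits each), and a
10,000-compound Gaussian null for hit-rule calibration. At these sizes the
whole suite completes in well under a minute of compute per component.

# Known limitations

* Threshold-based segmentation with one nucleus per cell; no watershed
  splitting of touching nuclei, no machine-learned segmentation, no
  3-D/time series.
* Connected components are 4-connected (the `EBImage::bwlabel` convention);
  diagonal-only bridges separate objects.
* The Chebyshev ring metric is the package's reading of "n pixel wide";
  Euclidean-disk rings would differ at corners. The metric is fixed
  package-wide rather than per-call.
* Plate normalization assumes control medians are trustworthy; no outlier
  rejection inside control sets, no spatial (row/column) correction.
* The 3-SD hit rule is implemented as stated, with no FDR layer and no
  dose–response confirmation; hit lists are candidates for orthogonal
  validation (e.g. western blotting), not final calls.
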