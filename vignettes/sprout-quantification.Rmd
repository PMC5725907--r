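---
title: "Quantifying bead-sprouting angiogenesis images with sproutr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bead-sprouting angiogenesis images with sproutr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sproutr)
```

## The assay and what is measured

In the fibrin-gel bead sprouting assay, endothelial cells (optionally
co-cultured with pericytes at a 10:1 endothelial-to-pericyte seeding ratio)
are coated onto dextran microcarrier beads of roughly 150--250 µm diameter
and embedded in a fibrin gel. Over days, multicellular, lumenized vascular
sprouts grow radially from the bead surface. Fixed cultures are stained —
F-actin (phalloidin) for the cell bodies, DAPI for all nuclei, Erg-1/2/3 as
an endothelial-specific nuclear marker, NG2 as a pericyte surface marker —
and imaged as z-stacks whose maximum intensity projections (MIPs) are
analyzed.

`sproutr` quantifies such projections in five configurable stages:

1. **Bead detection** — beads are large, bright, near-circular objects in
   the actin channel (cells coat the bead surface). The plane is smoothed
   (default sigma 2 µm) and thresholded, a morphological opening with a
   disc of half the minimum bead radius detaches the thin sprouts, and
   dark bead cores are hole-filled per label. The order matters: opening
   runs *before* hole filling, so a stray noise bridge between two
   converging sprouts can never close a loop that filling would turn into
   a phantom bead-sized object. Touching beads are separated by a
   distance-transform watershed seeded at regional maxima. Components pass
   gates on equivalent radius (default 50--150 µm) and circularity
   $4\pi A / P^2$ (default $\geq 0.6$).
2. **Sprout segmentation** — the actin plane is Gaussian-smoothed
   (`blur_sigma_um`, default 2 µm), thresholded, bead pixels removed, small
   gaps closed, and components below `min_sprout_area_um2` (default
   200 µm²) dropped. A component is *attached* when it overlaps the
   perimeter band (default 20 µm wide) of a bead; unattached debris is
   reported separately and excluded from per-bead statistics.
3. **Skeleton morphometry** — the sprout mask is thinned to a 1-px
   skeleton; sprout number, total/average length, average width
   (area/length), and branch points are read off the skeleton graph.
4. **Nuclei and classification** — DAPI blobs are detected, optionally
   watershed-split, gated by area (default 50--400 µm²; an 8 µm nucleus
   projects to ~50 µm²), and classified EC vs. pericyte by the presence of
   the nuclear endothelial marker.
5. **Pericyte coverage** — the NG2 plane is thresholded and coverage is
   the fraction of (bead-attached) sprout area overlapped by
   marker-positive signal; the raw marker-positive area is reported
   separately in µm².

All geometry is reported in micrometers through a user-supplied pixel
size. Pixel size is deliberately *not* read from file metadata: screening
datasets are routinely re-saved by stitching tools that mangle calibration
tags, so the calibration travels in the run configuration, and an unset
value falls back to 1 µm/px with a loud warning.

## Definitions the output table relies on

**Sprout number.** A bead's sprout count is the number of distinct skeleton
branches crossing the bead's perimeter band. This makes a distally
bifurcating sprout count once (its skeleton crosses the band once), which
matches how sprouts are counted by eye at the bead surface. Counting
connected components instead is available via `count_mode = "components"`.

**Length.** Each skeleton branch is measured by *chordal resampling*: the
branch path is ordered pixel-by-pixel and Euclidean chords are summed over
every 5th pixel. Per-pixel chain codes (1 for axial, $\sqrt 2$ for diagonal
steps) systematically overestimate straight digital lines by up to 8.3% at
intermediate angles (mean ≈ 5.5% over uniform orientations); chordal
resampling is exact at 0°, 45° and 90° and within ~1% elsewhere, which is
what makes the 5% length-recovery target attainable for sprouts at
arbitrary orientations. Thinning retracts the skeleton where a tube meets
the bead, so the gap between each band crossing and the bead boundary
(measured on the bead distance map) is added back to the total.

**Width.** The paper-facing "sprout width" is defined here as total
attached sprout area divided by total skeleton length — an area-weighted
mean width. It is parameter-free, stable under resolution changes, and
degrades gracefully for curved or branched sprouts.

**Branch points.** Skeleton pixels with ≥ 3 neighbours cluster into
8-connected junction groups; each group counts once (thinning yields 2--3
adjacent high-degree pixels at a single biological bifurcation). The
average divides by the *sprout* count, and a per-bead variant is available.
Spurs shorter than `prune_length_um` (default 10 µm) are pruned iteratively
before counting: they are thinning artifacts of rough mask edges and
would otherwise inflate branch counts.

**Classification.** For each nucleus a core marker intensity — the mean of
its brightest pixel quartile — is computed on the EC-marker plane; the
brightest-quartile statistic resists dilution by the dim rim of the
nucleus mask. The threshold between classes is an object-level Otsu on
these values, *accepted only when the distribution is actually bimodal*
(Ashman's $D \geq 3.5$; an Otsu split of a unimodal sample produces
$D \approx 2.7$ by construction). Otherwise the well is treated as
single-class and positivity is called against the plane background
(median + 2 MAD). This keeps degenerate wells — all-EC cultures, or
marker-free controls — from being force-split into two classes.

**Coverage.** The NG2 plane is smoothed with the same sigma as sprout
segmentation before thresholding, so marker and sprout boundaries sit on
comparable half-height contours; without this the coverage numerator
systematically misses the sprout rim and the estimate is biased by several
percentage points at high coverage. The automatic threshold is estimated
from the sprout neighbourhood (sprout mask dilated by 20 µm), where
positive and negative pixels are balanced, then applied globally —
plane-wide Otsu is unreliable when ribbons occupy one or two percent of
the field.

**Thresholds.** Stage thresholds default to Otsu's criterion except
nucleus detection, which defaults to the triangle method: nuclei cover a
tiny fraction of a well montage and Otsu's between-class criterion
collapses under that imbalance, placing the threshold inside the
background mode. The actin-based stages keep Otsu but threshold a
smoothed plane: shrinking the background variance removes the payoff
Otsu would otherwise find in splitting the background mode when the
foreground is sparse, so the threshold stays in the valley between
background and signal even for a single small bead in a large field. Every stage accepts a manual level, and `tune_params()`
freezes the automatic levels of a representative image into a
configuration so an entire dataset can be processed with identical
parameters.

## Plate-level statistics

Screening plates contain repeated wells per condition across several
assays. `aggregate_wells()` collapses wells to one value per condition and
assay using bead-count weights
$\bar x = \sum_w x_w n_w / \sum_w n_w$ — wells with more beads contribute
proportionally more sprouts to the estimate, and zero-bead wells are
excluded with a warning. `normalize_to_control()` divides each condition's
per-assay value by the control condition sharing the compound's solvent
(PBS-dissolved compounds against the PBS control, DMSO against DMSO), so a
control condition normalizes to exactly 1. `test_condition()` then applies
a two-sided one-sample t-test of the per-assay fold changes against 1,
with significance tiers at 0.05 and 0.01 reported side by side.

Two orderings are deliberate and documented rather than prescribed by any
single source: wells are collapsed *before* normalization, and
normalization is per-assay (each assay's conditions divided by that
assay's own control) *before* pooling across assays. The unit of
replication for the t-test is the assay, not the well — collapsing first
avoids pseudo-replication, and per-assay folds are what a t-test against
1.0 presupposes, since primary-cell assays shift in level between
repetitions. No multiple-testing correction is applied across compounds;
the two p-value tiers mirror screening practice, and users comparing many
compounds should treat the 0.05 tier as exploratory.

## The synthetic scene generator

`random_scene()` and `render_scene()` produce multi-channel images with
exact ground truth for every output: beads as bright discs; sprouts as
stroked polylines with hemispherical caps and mild waypoint curvature,
rasterized at exactly their nominal arc length; nuclei as Gaussian blobs
seeded along tube centerlines and on bead surfaces, trimmed so the
EC:pericyte count ratio is exactly 10:1; NG2 ribbons painted over a
controlled fraction of each tube's arc length; and optics as a Gaussian
PSF (default sigma 2 µm) followed by Poisson shot noise over a constant
background. SNR is defined as signal amplitude over background noise SD
and defaults to 5. Ground truth (areas, coverage) is computed from the
pre-noise masks, so discretization is part of the truth, not an error
source.

Default problem sizes used by the test-suite and the acceptance script —
fields of 700--1100 µm at 1 µm/px, 1--6 beads, 2--6 sprouts per bead of
150--400 µm — were chosen to mirror single-bead to small-montage fields
while keeping a full run of the suite within a few minutes.

What the generator deliberately does *not* emulate: uneven illumination
and vignetting, fibrin autofluorescence texture, overlapping or crossing
sprouts from neighbouring beads, partial z-coverage artifacts in MIPs,
lumen contrast, and anastomoses. Passing the recovery benchmarks therefore
demonstrates correctness of the measurement chain under controlled
degradation — not segmentation robustness on arbitrary real-world montages,
where per-dataset threshold tuning (the `tune` workflow) remains the
user's responsibility.

## Numerical choices and degenerate inputs

* Thinning is Zhang–Suen with a sequential simple-point cleanup pass
  (Yokoi connectivity number 1, endpoints protected), giving minimally
  thin, 8-connected skeletons without staircase side-junctions.
* Watershed ties and label order are deterministic; component labels are
  assigned in raster-scan order, so repeated runs are bit-identical.
* Zero beads, zero sprouts, or empty planes are valid results, not errors;
  averages over empty sets are reported missing (`NA`), never zero, and
  missing values propagate as missing through aggregation.
* Components touching two beads (anastomoses) are assigned to both beads
  and flagged; their area and length are counted once in image totals.
* Beads clipped by the field border are counted if their visible shape
  passes the gates, and flagged `touches_border`.
* A sprout component must carry at least `min_sprout_length_um` of
  skeleton (default 20 µm) for its band crossing to count as a sprout.

## Known limitations

* Measurements are 2D projections: widths and areas of overlapping sprouts
  are not disentangled, and lumenization is not assessed.
* The area/length width definition underestimates the width of strongly
  tapered sprouts relative to their widest point; a maximum-inscribed-disc
  variant can be derived from the distance transform if needed.
* Classification assumes the EC marker is nuclear and colocalizes with
  the nucleus mask; cytoplasmic markers would need a different statistic.
* The t-test assumes approximate normality of per-assay fold changes; with
  N = 3 assays this is an approximation inherited from the screening
  design it reproduces.
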