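---
title: "cortexflat: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cortexflat: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexflat)
```

## The problem

Retrograde tracing asks which regions project to an injected cortical
site: a tracer (cholera toxin-B, Fluoro-Gold) deposited in cortex is
transported back along axons and accumulates in the somata of projection
neurons throughout the brain. Quantifying such an experiment across a
whole brain means (1) detecting every neuron in NeuN-stained sections,
(2) deciding which detected neurons actually contain tracer, (3) placing
positive neurons into a common anatomical frame so sections and animals
can be compared, and (4) turning per-region counts into statistics that
survive differences in injection size and detection efficiency.

`cortexflat` implements this pipeline end to end, together with a
synthetic-histology generator that plants neurons with known positions,
intensities and region memberships, so that every stage can be tested
against exact ground truth. Nothing in the package requires real data.

## Detection and classification

Neurons are detected in the NeuN channel by a deliberately simple,
fully specified detector: Gaussian smoothing (sigma 1 px), an Otsu
threshold on the smoothed channel (an absolute threshold can override
it), 8-connected components, a marker-based watershed on the chamfer
distance transform to split touching somata, and a minimum-area filter.
The original analysis treated segmentation as a black box (an external
segmentation tool); the replacement here is intentionally transparent
and swappable, and its parameters (`threshold`, `min_area`, `sigma`,
`min_peak_dist`) are module defaults, not reconstructions of the
original tool's settings.

Per cell, `extract_features()` reports the intensity-weighted centroid
(0-based pixel coordinates, origin top-left, x rightward, y downward)
and, for every channel, the integrated intensity — the sum of pixel
values over the segmented footprint — plus the maximum and minimum
pixel value. Large rasters can be processed in overlapping tiles;
duplicate detections in an overlap band are resolved by keeping the
detection whose centroid lies farthest from its own tile border, which
is deterministic and symmetric.

A cell is classified retrograde-tracer positive when, in the tracer
channel, integrated intensity exceeds 250,000 **and** the maximum pixel
exceeds 150 (8-bit pixels, 0–255). Both comparisons are strict:
"exceeds" is read literally, so boundary equality is negative. The rule
is a conjunction and monotone in both features. Both thresholds are
plain parameters of `classifier_params()`, because the published values
are tied to full-resolution somata (0.23 µm/px); the scaled-down
synthetic sections use thresholds placed between the planted positive
and negative intensity ranges instead (see below).

## Count calibration

Automated counting systematically undercounts relative to manual
counting. The correction regresses manual counts (response) on
automated counts (predictor), per animal, and adds the magnitude of the
negative x-intercept (`-intercept/slope`) to every automated count on
the analysis inclusion list. The orientation deserves a note: with
manual as the response, a constant undercount of `k` gives intercept
`+k` and x-intercept `-k`, so the offset "added to each automated
count" is exactly `|x-intercept|` — the only orientation consistent
with uniformly negative published x-intercepts alongside positive added
offsets. A non-positive slope flags the model unusable; a positive
x-intercept leads to an adjustment of 0 (the correction never decreases
a count). Adjustment happens before injection-site zeroing; the order
is fixed.

For animals whose labeling is too weak for reliable automated counting,
the calibration path can be bypassed entirely by supplying manual
counts sampled at the automated interval (the pipeline consumes any
per-ROI count table).

## Flat maps

Each section contributes one row of the flat map. The layer IV/V
boundary is traced as an ordered polyline, resampled to uniform 1-px
arc spacing, and smoothed by a moving-window line regression: every
vertex is replaced by the centre-point evaluation of a least-squares
line fitted over the `window` (default 5) vertices centred on it, with
shrunken one-sided windows at the ends. At 0.23 µm/px the defaults
correspond to a 1.15 µm window advanced in 0.23 µm steps. Whether the
original smoother operated on raw vertices or an arc-parameterised
resampling is not stated anywhere; the resampled reading was chosen
because it makes the window's micrometer equivalence exact, and it is
recorded here as a package decision.

Every tracer-positive cell is dropped perpendicularly onto its
section's smoothed line (segment-wise orthogonal projection, clamped to
segment ends — coordinates stay bounded rather than extrapolating).
Its coordinate is the signed arc length from the cingulum-border
anchor: negative medial, positive lateral, toward the rhinal-sulcus
landmark. Ties between equidistant segments break toward the smaller
arc position, deterministically. Arc positions depend only on
distances along and to the line, so they are invariant under rigid
transforms of a section; the tests verify this to 1e-6 µm.

Rows are keyed by anterior-posterior position (a millimetre analog on a
0.05 mm/section grid), not by raw section index, so that replacing a
damaged section with its neighbour leaves the map plottable. Cells in
the injection ROI(s) stay visible on the map but are flagged out of the
quantification layer.

## ROI analysis

ROI polygons are inputs (hand-drawn in the real workflow, generated
along the ribbon in the synthetic one); no atlas registration is
attempted. Cell-to-ROI assignment uses an even-odd point-in-polygon
test with boundary points counted inside; when polygons overlap —
hand-drawn ROIs are assumed disjoint, so this is a warning — the first
ROI in deterministic name-sorted order wins. Counting reads only cell
coordinates, never tracer values, mirroring the blinding of ROI drawing
to the tracer channel.

The injection ROI (or two, when the deposit straddles a border) is
zeroed on every section before proportions are formed; proportions are
counts over the total across included ROIs and sum to 1 by
construction. Aggregation maps ROIs onto the four cortical networks
(medial, lateral, somatic, claustrum/entorhinal) or onto thalamic
groups. The default cortical map is a 21-ROI table assembled from the
published region lists; those lists are not exhaustive, so the map is a
default meant to be overridden per study. The thalamic grouping uses
seven levels — motor, sensory, anterior-, lateral- and
mediodorsal-associative, intralaminar, midline — following the reported
degrees of freedom (which imply 7 levels) rather than the five-group
prose; this discrepancy is deliberate and flagged.

Injection placement is quantified as the arc distance of the injection
centre from the medial cingulate border in the flat-map frame;
medial/lateral and rostral/caudal classes come from configurable
boundaries, with a centre exactly on the boundary classified medial
(logged tie rule). Anterograde experiments are handled by the same
zeroing-then-normalising logic applied to per-ROI integrated terminal
intensity.

## Repeated-measures ANOVA

Regional and group comparisons use classical uncorrected
repeated-measures decompositions, implemented as explicit sums of
squares (the printed analyses report uncorrected degrees of freedom):

* one-way within-subject: `F = MS_region / MS_error` on
  `(k-1, (k-1)(n-1))` df;
* split-plot two-way: the group effect is tested against subjects
  within groups on `(g-1, N-g)` df; region and the group-by-region
  interaction against the within-subject error on `(k-1, (k-1)(N-g))`
  and `((g-1)(k-1), (k-1)(N-g))` df.

The implementation is cross-checked in the test suite against
`stats::aov` with an `Error(subject)` stratum — an independent route —
to 1e-9, including unbalanced group sizes (4 vs 5 animals). A
Greenhouse–Geisser correction is available behind `gg = TRUE` and off
by default. Incomplete designs are rejected rather than imputed. When
an effect's sum of squares is exactly zero while the error stratum is
also degenerate, F is reported as 0 rather than 0/0. Bonferroni
post-hoc tests are paired t-tests with p multiplied by the number of
comparisons actually tested (the family is passed explicitly, because
the published families vary by figure) and capped at 1. Significance
is assessed at alpha = 0.05, configurable.

## The synthetic world

`synth_params()` fixes the stated world; the defaults are chosen once:

* raster 1200 × 400 px at 0.23 µm/px — a scaled-down section, the
  published pixel pitch;
* a cortical ribbon drawn as a natural spline through control points
  (shallow arc), half-width 40 px, with the cingulum anchor at the
  medial end and the rhinal-sulcus landmark near the lateral end;
* 150 neurons per section, 40 tracer-positive, paint radius 4–6 px as
  isotropic Gaussians with sigma = radius/3 clipped at 3 sigma
  (footprints never overlap at the 13 px minimum separation), additive
  with saturation at 255;
* NeuN peak amplitude U(120, 220); tracer peak U(150, 255) for
  positives vs U(0, 30) for negatives; Gaussian background noise
  sd 2; all channels 8-bit;
* the tracer is written into a dedicated channel (blue = NeuN,
  red = CTB, third channel = Fluoro-Gold) — how the yellow Fluoro-Gold
  signal distributes over acquisition channels is not stated anywhere,
  so a dedicated channel avoids cross-channel ambiguity;
* placement by rejection sampling with 1000 retries per cell, erroring
  explicitly on infeasible packing; everything runs through one seeded
  generator, so a fixed seed reproduces sections bit for bit.

Ground truth stores each cell's centre, positivity, ROI, arc position
on the noiseless curve, and per-channel integrated intensity summed
over the painted footprint of the noise-free raster (so the brute-force
check is exact only at noise 0, by design). Brains emulate the
sectioning scheme: three parallel series, the NeuN series being every
third cut section, a map for every other NeuN section — exactly 1/6 of
cut sections mapped when the count divides by 6. Unmapped series
sections keep geometry and truth but skip rasterisation by default, to
stay inside time and memory budgets.

Because synthetic somata are an order of magnitude smaller in area than
full-resolution somata, their integrated intensities live in the
thousands, not the hundreds of thousands; classification on synthetic
images therefore uses thresholds placed between the planted ranges
(1200 / 75 in the demo configuration), while the published 250,000/150
rule is exercised on synthetic feature tables whose distributions
straddle it with a ≥10 % margin.

For calibration fixtures, per-ROI true counts are modelled as
8 + round(LogNormal(meanlog 2.5, sdlog 1.3)): heavy-tailed, median
around 20 with occasional hub-region counts in the hundreds, floored
so the undercount clamp `max(0, true - offset + noise)` never binds.
The heavy tail reflects real per-ROI count tables, where one or two
regions dominate; it also gives the regression the leverage the
x-intercept needs, since its standard error scales with
`sqrt(1/n + mean(x)^2 / Sxx)`.

What a green test does **not** establish: the generator has no staining
artifacts, tissue tearing, section-to-section deformation, realistic
textures, anisotropic somata, or cross-channel bleed-through, and no
nonrigid deformation between sections. Results on synthetic sections
bound algorithmic correctness, not histological robustness.

## Numerical conventions

* Coordinates are 0-based pixel centres; matrices are indexed
  `[y + 1, x + 1]` internally.
* Chamfer 3-4 distances are divided by 3, so a unit step costs 1 px.
* Otsu maximises between-class variance over the 256-bin histogram.
* `resample_polyline()` interpolates linearly at uniform arc spacing;
  landmark indices are re-attached to the nearest vertex by position
  after any resampling or smoothing.
* Projection ties break toward the smaller arc position (1e-9
  tolerance); degenerate zero-length lines are an error.
* Rasters above 8-bit are rescaled into 0–255 with a logged factor.
* The pipeline config is JSON (no YAML parser is assumed); geometry is
  JSON, rasters are ASCII PGM per channel, tables are CSV. The
  manifest records per-stage parameters, seeds and MD5 checksums, and
  `run_pipeline()` skips stages whose outputs exist under an unchanged
  fingerprint, so deleting one stage's outputs reruns just that stage.

## Known limitations

* The watershed split is tuned for roughly convex somata; heavily
  interdigitated cells may merge or oversplit.
* Hemisphere handling is minimal: cells carry an optional hemisphere
  label and `filter_ipsilateral()` drops contralateral ones; no
  mirroring registration is performed.
* The ANOVA module covers the split-plot designs used here, not general
  mixed models; missing cells are rejected, and published df that imply
  incomplete designs are not reverse-engineered.
* ROI polygons must be simple; self-intersection is an error, not a
  repair.
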