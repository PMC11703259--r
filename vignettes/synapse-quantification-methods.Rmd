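---
title: "Methods: quantifying synaptic protein localization, ultrastructure and calcium signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying synaptic protein localization, ultrastructure and calcium signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synquant)
```

This vignette documents the models, parameters and numerical choices behind
`synquant`. The package quantifies three readouts of synaptic endocytosis in
cortical tissue: STED localization of Dyn1xA relative to the active zone,
electron-micrograph morphometry of endocytic structures, and two-photon
calcium line scans. Every stage is validated against a seeded synthetic-data
generator with exact ground truth; the test suite and `scripts/acceptance.R`
state the empirical performance, and nothing is claimed here that they do
not compute.

## Image model and preprocessing

Images are three-channel rasters at 20 nm/pixel (CH1 Bassoon, CH2 PSD95,
CH3 Dyn1xA), held as lists of matrices indexed `[row, col]`, 1-based, with
pixel centers at integer coordinates. Angles are degrees counter-clockwise
from the +column axis; undirected (axial) angles live in `[0, 180)`.

Preprocessing follows the standard STED chain:

* **Min–max normalization** per channel to `[0, 1]`. A constant channel maps
  to all zeros — the explicit division-by-zero guard for degenerate crops.
* **Gaussian pre-filter**, default σ = 1.2 px. A "1.2 pixel radius" filter
  is interpreted as the Gaussian standard deviation, the common imaging
  convention; the value is a tunable argument.
* **PSF measurement** from isolated non-specific antibody puncta:
  background (median of the patch border ring) is subtracted, patches are
  clipped at zero, averaged, recentered on their maximum and normalized to
  unit sum. Patches overlapping the image border are skipped with a warning.
* **Two-step blind deconvolution.** Blind Richardson–Lucy alternates one
  multiplicative image update and one multiplicative PSF update per
  iteration (10 iterations per run). The first run refines the measured PSF
  ("enhanced" PSF, its restored image discarded); the second run deconvolves
  the original pre-filtered image with the enhanced PSF. The cited blind
  scheme is not fully specified anywhere public, so the update schedule is
  fixed and documented here; its contract is property-level: non-negativity
  everywhere, PSFs non-negative with unit sum, a delta PSF is an exact fixed
  point, total flux conserved to 10⁻⁶ relative on interior scenes, and
  restored point sources never move by more than 1 px.

All convolutions use **reflective padding**, chosen so flux is not lost at
the boundary of 45 × 45 px regions of interest. Division inside
Richardson–Lucy guards with the machine epsilon.

## Segmentation

Candidate synapses are local maxima of the σ = 2 px smoothed Bassoon channel
above 25% of its dynamic range that carry Dyn1xA signal (≥ 10% of the Dyn1xA
maximum) within the prospective ROI; maxima closer than 20 px merge, keeping
the brighter. ROIs are fixed 45 × 45 px crops (center pixel at (23, 23));
candidates whose ROI would cross the image border are skipped with a logged
warning.

View sorting replaces the interactive supervision used in practice with a
deterministic rule: Otsu-threshold the Bassoon crop, take the largest
4-connected component (ties break to the lowest raster-order label), and
compute the elongation of its moment ellipse (major/minor axis ratio, with
a 1/12 px² pixel-variance correction). Elongation ≥ 1.8 ⇒ *side* view,
≤ 1.4 ⇒ *top* view, otherwise *rejected*. The thresholds are exposed
arguments; they are package choices, since no quantitative sorting criterion
is published.

Pixel classification is likewise a headless stand-in for an interactively
trained classifier: a feature stack of Gaussian-smoothed intensity and
gradient magnitude at the seven standard scales
σ = 0.3, 0.7, 1.0, 1.6, 3.5, 5.0, 10.0 px feeds either Otsu on the σ = 1.0
smoothed intensity (default) or a logistic model trained on labeled
fixtures. Otsu runs on min–max normalized intensities with a fixed 256-bin
histogram, which makes masks invariant to affine intensity rescaling by
construction. Foreground polarity is enforced by mapping the class with the
higher mean smoothed intensity (the bright object class) to 1.

## Side-view geometry

The largest external contour of each scaffold mask (sub-pixel, marching
squares at level 0.5) is fit with an ellipse by direct least squares
(constrained conic fit on centered coordinates). The fit needs at least 5
contour points; smaller masks raise an "unanalyzable" error. The major-axis
angle is normalized to `[0, 180)`.

The **center-line** is parallel to the averaged major axes through the
midpoint of the two ellipse centers; its length is the mean major-axis
length. Axes differing by ≤ 30° (axially) are averaged on doubled angles
(so 179° and 1° average to 0°, not 90°); otherwise both axes become unit
vectors — the second flipped into the half-plane of the first, which makes
the atan2 average well defined — and their sum's direction is used. An
exactly antipodal (zero-norm) sum falls back to the axial average with a
warning. Perpendicular axes have no defined axial mean; they always take
the vector branch.

The ROI is rotated about its center by `90° − angle` so the center-line is
vertical. Interpolation is Catmull–Rom bicubic; values undefined after
rotation fill with the channel mean, so constant channels are exact fixed
points. (A fifth-order spline is the convention in one reference
implementation; bicubic was chosen here as the best interpolator available
without new compiled code, and end-to-end recovery stays within the 1 px
contract on all fixtures.) Orientation is standardized by comparing the
rotated Bassoon/PSD95 mask centroids and applying a 180° flip so Bassoon
lies right of the center-line; equal centroids warn and leave the ROI
unflipped.

The **band line scan** averages, per column, the 42 rows centered on the
image midline — rows `center − ⌊w/2⌋ … center + w/2 − 1`, i.e. rows 2..43
of a 45-row ROI; the rounding rule is fixed and documented. Profiles are
min–max normalized per channel, and x is recentered on the ROI's central
column (column 23), left negative, right positive, ×20 nm. The recentering
origin is a package choice: rotation is about the ROI center and the
center-line anchor (midpoint of the ellipse centers) maps next to it for
any centered synapse; using the central column keeps the x-grid uniform.

Peaks are plain local maxima (plateaus resolve to their middle sample) with
a strict amplitude gate: only peaks with normalized amplitude **> 0.5** are
retained — a peak of exactly 0.5 is rejected. Peaks are called on the
Dyn1xA channel by default; the channel set is an argument, since scaffold
peak positions are also of interest.

## Top-view geometry

Dyn1xA puncta are local-maxima pixels: 8-neighborhood maxima where every
pixel just outside the equal-valued plateau is strictly lower, plateaus
resolving to their centroid pixel; a prominence gate (as a fraction of the
channel maximum, default 0.3) suppresses noise maxima. The active-zone
boundary for each Bassoon maximum is the sub-pixel iso-contour at **half
that maximum's intensity**, extracted by marching squares with linear
interpolation; the closed contour enclosing the maximum is selected.
Contours truncated by the ROI edge are flagged *crossing* and excluded.

Signed distances are minimum point-to-**segment** distances over the closed
contour (strictly more accurate than vertex-only sampling; the test suite
bounds the difference), negative inside the contour (even–odd rule). With
several active zones in one ROI, each punctum is assigned to the boundary
with the smallest absolute distance. Exclusions: puncta whose half-max
support region touches the ROI border ring, boundaries flagged crossing,
and (when a neuron mask is supplied) Bassoon maxima outside it; all drops
are logged with reasons. The periactive-zone fraction counts distances in
the band **−50 to +50 nm inclusive on both ends**; the published interval
carries no open/closed marking, so inclusivity is fixed and documented.

## EM morphometry

Annotations are plain text, one feature per line
(`profile_id TAB class TAB polyline|polygon TAB x1,y1;x2,y2;…`, with a
`# scale_nm_per_px` header); the parser validates classes, vertex counts and
numeric coordinates and names the offending line on error. Vesicular
polygons are classified from geometry — equivalent-circle diameter
D = 2√(area/π) and circularity c = 4π·area/perimeter²: D ≥ 100 nm ⇒
endosome (inclusive), D > 60 nm with c < 0.8 ⇒ endosome (oblong rule),
60 < D < 100 nm ⇒ large vesicle, else synaptic vesicle. A 10⁻⁹ nm
tolerance at the 60 and 100 nm bounds keeps floating-point noise from
flipping a polygon whose exact diameter sits on a bound. Pit coat state
(uncoated vs clathrin-coated) always comes from the annotation label — it
is a human judgement, never inferred.

Pit distance to the active zone is measured **along the membrane**: pit
base points (polyline endpoints) and active-zone endpoints are projected
onto the membrane's arc-length parameterization (projections farther than
2 px off the membrane are errors), and the distance is the gap between the
two intervals, zero if they touch or overlap. A Euclidean mode is provided
for comparison, since the published phrase "nearest edge" does not fix the
metric; arc-length is the default because the annotation convention
measures along the plasma membrane. Pit **neck width** is the base-chord
length and **diameter** the maximum extent parallel to the base chord —
definitions fixed here because none are published; for bulbous (omega-like)
pits the diameter exceeds the neck, for shallow arcs the two coincide.

Pooled values use the sample median with the exact binomial order-statistic
95% CI (no distributional assumption, matching a "median ± 95% CI"
reporting convention without inventing a bootstrap); for n < 6 no such
interval exists and the data range is reported with a `method = "range"`
flag. The operation is exported as `median_ci()` — the natural name
`summarize` would collide with the dplyr verb.

## Calcium line scans

dF/F₀ uses the mean raw intensity over a pre-stimulus window (default
0–60 ms before a first stimulus at 70 ms; at least 3 samples; F₀ ≤ 0 is an
error). The indicator darkens with calcium, so transients are negative.
The recovery from the post-stimulus extreme is fit with
v(t) = A·exp(−(t − t₀)/τ) + C by Levenberg–Marquardt least squares
(`minpack.lm`), initialized from the segment endpoints with τ₀ = span/3;
the revealed *minimum* is the fitted extreme A + C at the segment start.
Near-constant segments short-circuit to A = 0 with the mean as minimum.

"Normalization to the minimum" is implemented as
value = 1 + (v − baseline)/|min − baseline|, mapping the baseline to 1 and
the fitted minimum to 0 — the convention of the published trace plots,
where a dotted baseline sits at y = 1 and the trace dips toward 0. The
transform is idempotent (re-applying with baseline 1, minimum 0 is the
identity) and gain-invariant (dF/F₀ input is already gain-free). When
comparing stimulus conditions *within* a slice, one shared reference
minimum per slice should be passed (`min_reference` in
`analyze_calcium_trace()`); normalizing each trace by its own minimum
would, by design, erase amplitude differences. The signal area is the
trapezoidal integral of (baseline − value) on the native time grid from
the first stimulus (70 ms) to the end of the scan (900 ms), positive for a
dip; no resampling is performed.

## The synthetic generator

The generator defines the study conditions for every test:

* **Side view**: two parallel bars (line segments convolved analytically
  with an isotropic Gaussian, via erf) separated by 150 nm — the typical
  Bassoon-to-PSD95 epitope distance of an excitatory synapse — each 400 nm
  long, plus isotropic Gaussian puncta at signed offsets from the midline
  (positive toward Bassoon). PSF σ defaults to 60 nm, a typical effective
  STED resolution.
* **Top view**: an isotropic Gaussian blob whose analytic half-max radius
  *is* the nominal active-zone radius (150 nm; the blob σ absorbs the
  optics, σ = r/√(2 ln 2)), with puncta planted at radius r + d at evenly
  spaced, seed-rotated azimuths — so each punctum's true signed distance to
  the half-max boundary is exact by construction.
* **Noise**: Poisson shot noise on expected photon counts after blurring,
  peak expectation `photon_scale` = 200 by default; `photon_scale = Inf`
  disables noise for oracle tests (the noiseless scene then has unit peak).
  No detector read noise or depletion-beam physics is modeled, and no 3-D
  stacks — the analyses are strictly 2-D. Published acquisitions report no
  photon statistics, so the default is a package choice at which the ±1 px
  recovery contract is demanded by the tests.
* **EM**: per-profile Poisson counts (0.8 uncoated pits, 0.6 large
  vesicles, 0.5 endosomes, 0.15 coated pits, 8 synaptic vesicles on
  average), a straight 3 µm membrane (so arc length equals Euclidean length
  and planted gaps are exact), circular-arc pits with 40–80 nm necks and
  shallow-to-bulbous depths, exponential nearest-edge gaps (mean 15 nm),
  and area-true polygons for vesicles/endosomes (vertex radius scaled so
  the shoelace area equals the analytic area exactly, making
  size-threshold tests exact). Pits on a flank are laid out sequentially;
  the *realized* gap of every pit is returned as truth.
* **Calcium**: exponentially decaying baseline (amplitude 5 on asymptote
  95, τ = 2 s) plus negative transients (default −40, τ = 250 ms) at the
  stimulus times, plus white Gaussian noise (σ = 1), on a 0–900 ms grid at
  2 ms.

All randomness flows from one master seed through a documented splitting
scheme (`split_seed()`: seed + a string hash of the stream label, modulo
2³¹ − 1), so every fixture is bit-reproducible and adding a stream never
perturbs existing ones.

What passing tests do **not** show about real data: the generator draws
ideal Gaussian optics, isolated synapses centered in their ROIs, straight
membranes and clean annotation geometry. Real tissue adds background
staining, overlapping synapses, curved membranes, annotation noise and
label-density effects that the recovery rates here do not speak to.

## Problem sizes and runtime choices

The test suite uses 100-fixture cohorts for the side-view, top-view and EM
recovery properties (offsets −200..+200 nm, signed distances −100..+100 nm,
100 synaptic profiles), 1000 random polygon/point pairs for the
point-to-boundary oracle (dense resampling at 10⁻³ px, pairs closer than
0.5 px to the boundary regenerated because resampling cannot resolve them),
the full 1° × 1° axial-angle grid (perpendicular pairs excluded as
undefined), and 100 Monte-Carlo seeds for the noisy-τ recovery. The
acceptance script uses the same cohorts with 300 oracle pairs. These sizes
keep the full suite in a few minutes on one CPU while leaving the
statistical checks well-powered.

## Known limitations

* The blind-deconvolution update schedule is one member of a family; only
  its conservation/localization properties, not a specific reference
  output, are guaranteed.
* View sorting and pixel classification are deterministic stand-ins for
  human-supervised steps; their thresholds are honest tuning knobs.
* Sub-pixel punctum positions are not refined (local maxima are pixel
  centers), bounding localization at half a pixel (10 nm) before noise.
* The EM generator plants non-overlapping, well-formed geometry; the
  parser validates but does not repair malformed annotations.
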