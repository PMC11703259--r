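# synquant

Quantification of synaptic protein localization, ultrastructure and calcium
signals — an R package for the image- and annotation-analysis side of
time-resolved studies of synaptic vesicle endocytosis in cortical tissue.

## The scientific problem

Ultrafast endocytosis retrieves synaptic vesicle membrane within ~100 ms of a
stimulus, at a membrane band flanking the active zone (the *periactive* or
*endocytic zone*, roughly −50 nm to +50 nm around the active-zone edge).
Testing whether this machinery is in place in intact tissue requires three
quantitative readouts:

1. **STED localization.** Where does the endocytic dynamin isoform Dyn1xA sit
   relative to the active zone? Synapses are imaged in three channels
   (CH1 = Bassoon, presynaptic scaffold; CH2 = PSD95, postsynaptic scaffold;
   CH3 = Dyn1xA) at 20 nm/pixel. *Side-view* synapses (edge-on) are analyzed
   with a band line scan across the trans-synaptic axis: the Bassoon and
   PSD95 masks are fit with ellipses, the **center-line** is the line parallel
   to the averaged major axes through the midpoint of the two ellipse centers,
   the image is rotated so this line is vertical (Bassoon standardized to the
   right), and a 42-pixel band is averaged per column; Dyn1xA peaks with
   normalized amplitude > 0.5 are retained. *Top-view* synapses (face-on) are
   analyzed by taking the iso-contour at **half the intensity of each Bassoon
   local maximum** as the active-zone boundary and measuring the signed
   minimum distance from each Dyn1xA local-maximum pixel to that contour
   (negative inside). The fraction of puncta within −50..+50 nm summarizes
   endocytic-zone enrichment.
2. **EM morphometry.** Electron micrographs annotated per synaptic profile
   (plain-text polylines/polygons) are reduced to structure counts and sizes:
   uncoated/clathrin-coated pits with their nearest-edge distance to the
   active zone measured **along the plasma membrane**, pit neck width
   (base-chord length) and diameter (maximum base-parallel width), vesicle
   classes by equivalent-circle diameter *D* = 2√(area/π) and circularity
   *c* = 4π·area/perimeter² (*D* > 60 nm → large vesicle; *D* ≥ 100 nm, or
   oblong with *D* > 60 nm → endosome), and endosome areas (shoelace).
   Pooled values are reported as median with a distribution-free binomial
   95% CI.
3. **Calcium line scans.** Fura-2 AM darkens with rising calcium, so
   transients are negative-going. Traces are converted to dF/F₀ over a
   pre-stimulus baseline, the recovery is fit with *v(t) = A·e^(−t/τ) + C*
   to reveal the fitted minimum, traces are normalized so baseline → 1 and
   minimum → 0, and the signal area integrates (baseline − trace) from the
   first stimulus (70 ms) to the end of the scan (900 ms).

Preprocessing for STED uses min–max normalization, a σ = 1.2 px Gaussian
pre-filter, and **two-step blind Richardson–Lucy deconvolution**: a first
blind run (10 iterations) refines a PSF measured from non-specific antibody
puncta; the refined "enhanced" PSF then deconvolves the original image in a
second blind run.

Because raw micrographs and STED stacks are not redistributable, the package
ships a fully seeded **synthetic-data generator** that renders side-view and
top-view synapses (bars/blobs + puncta, Gaussian PSF, Poisson shot noise),
EM annotation files and calcium traces with exact ground truth, so every
stage of the pipeline is testable end-to-end.

## Worked example

```r
library(synquant)

# a side-view synapse with a Dyn1xA punctum 60 nm on the Bassoon side
r   <- render_sideview(sideview_truth(punctum_offsets_nm = 60, seed = 42))
img <- gaussian_prefilter(normalize_minmax(r$image), radius_px = 1.2)
res <- sideview_profile(img)
res$peaks
#> # A tibble: 1 × 3
#>   channel  x_nm amplitude
#>   <chr>   <dbl>     <dbl>
#> 1 Dyn1xA     60         1
```

The called peak sits at +60 nm — right of the center-line, on the Bassoon
(presynaptic) side, exactly where the punctum was planted.

```r
# top view: puncta at -40 (inside the AZ) and +30 nm from its edge
tv <- render_topview(topview_truth(punctum_distances_nm = c(-40, 30), seed = 42))
d  <- topview_distances(tv$image, presmooth_sigma_px = 1.2)
d
#> # A tibble: 2 × 5
#>     row   col boundary_id signed_distance_nm inside
#> 1    25    14           1               35.8 FALSE
#> 2    22    28           1              -51.9 TRUE
distance_summary(d$signed_distance_nm)$fraction_in_band
#> [1] 0.5
```

Both puncta are recovered within one pixel (20 nm) of their planted signed
distances (shot noise at the default photon budget accounts for the rest),
and one of the two falls in the −50..+50 nm periactive band.

```r
# a synthetic EM cohort: 50 profiles, pooled pit distances
fx  <- make_em_fixture(em_fixture_truth(n_profiles = 50, seed = 42))
met <- em_profile_metrics(parse_annotations(fx$text))
median_ci(met$pits$distance_to_az_nm)
#> # A tibble: 1 × 5
#>       n median ci_low ci_high method
#> 1    58   12.2   8.09    17.3 binomial
```

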