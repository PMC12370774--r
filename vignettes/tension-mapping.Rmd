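---
title: "Mapping fibronectin fiber tension in microthrombi: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping fibronectin fiber tension in microthrombi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tensiomap` quantifies the mechanical state of fibronectin fibers in
multichannel immunofluorescence images. This vignette explains the
measurement model, the parameters that matter, what the synthetic scene
generator does and does not emulate, and the numerical and design
choices made where the problem left the design open.

## Measurement model

Two channels carry the tension readout. A polyclonal anti-fibronectin
antibody (channel `FN`) stains all fibronectin fibers regardless of
strain. The Cy5-FnBPA5 peptide probe (channel `FNBPA5`) binds only
untensed fibers: its multivalent binding motif is disrupted when a fiber
is stretched, so probe signal on a fiber pixel means that pixel's fiber
is relaxed. Two further channels support cell analysis: `CD31`
(platelets, endothelium, some leukocytes) and `DAPI` (nuclei), whose
combination CD31+/DAPI− identifies anucleate platelets.

The pipeline's core quantities:

* **Joint mask and ratio map.** Each of FN and FNBPA5 is thresholded
  with Otsu's method; "positive" means strictly above the threshold.
  The ratio map `FNBPA5 / FN` is defined only where both channels are
  positive (the joint mask) — elsewhere the ratio would be dominated by
  background and is reported as undefined rather than imputed.
* **Untensed-pixel density** (the headline scalar):
  `100 · |FNBPA5+ ∧ FN+| / |FN+|`. The numerator is restricted to
  probe-positive pixels *inside* the FN mask, which guarantees a value
  in [0, 100] and matches the reading "percentage of all fibronectin
  fibers"; the unrestricted numerator would not be a percentage of
  anything.
* **Tension-class masks.** A classifier partitions the FN-positive
  universe into `untensed` and `stretched = FN+ ∧ ¬untensed`.
  Complementing *within* the fiber mask is deliberate: probe-negative
  background is not stretched fiber, and letting it into the stretched
  class would collapse every platelet-to-stretched distance toward 0.
* **Proximity.** For each tension mask, the exact Euclidean distance
  transform (distance from every pixel center to the nearest
  mask-positive pixel center, times the pixel size) is sampled at each
  platelet centroid with bilinear interpolation. Distances are
  centroid-to-pixel by construction — platelet centers, not boundaries.
* **Statistics.** Group comparisons run a four-test normality battery —
  D'Agostino–Pearson K², Anderson–Darling, Shapiro–Wilk, and
  Kolmogorov–Smirnov in its Lilliefors form (parameters estimated from
  the sample, as Prism's normality KS does) — and call the groups
  parametric when at least 3 of the 4 tests fail to reject at
  α = 0.05. Two parametric groups get an unpaired pooled-variance
  Student's t-test (Welch behind a flag); otherwise a two-sided
  Mann–Whitney test, exact (full permutation enumeration, tie-safe) up
  to a combined n of 20 and a tie-corrected, continuity-corrected
  normal approximation beyond.

## Tension classifiers

Three interchangeable classifiers produce the untensed/stretched
partition:

1. **Intensity baseline** (`"threshold-baseline"`): Otsu on raw FNBPA5
   restricted to the fiber mask. Simple, and kept verbatim as the floor
   the trained model must beat.
2. **Ratio baseline** (`"ratio-baseline"`, the pipeline default): Otsu
   on the background-subtracted FNBPA5/FN ratio restricted to the fiber
   mask. The PSF dilutes both channels equally at fiber rims, so the
   ratio stays informative exactly where raw probe intensity drops
   below threshold. Without this, the one-pixel blur halo around every
   relaxed patch is mislabeled "stretched", which poisons
   distance-to-stretched statistics (a stray stretched pixel near a
   platelet collapses its distance).
3. **Random forest** (`train_pixel_classifier()`): a probability forest
   (ranger, 200 trees, mtry = ⌊features/3⌋, fixed seed, single thread
   for bit reproducibility) over per-pixel multiscale features — raw
   intensity, Gaussian-smoothed intensity, gradient magnitude and
   Laplacian at σ ∈ {1, 2, 4} px for the FNBPA5 and FN channels.
   Annotations are positive/negative pixel masks (label PNGs:
   0 unlabeled, 1 negative, 2 positive); training holds out a
   stratified 20% of annotated pixels and reports held-out accuracy,
   flagging chance-level models. The decision threshold on the
   untensed-class probability defaults to 0.5.

## Platelet detection and gating

CD31 segmentation is smoothing (σ = 2 px) → Otsu → connected components
(8-connectivity) → optional watershed split of touching blobs → area
filter. The default area bounds, 1–20 µm², are the platelet scale and
the most consequential detector setting: widen `max_area_um2` if larger
nucleated cells must be retained. Centroids are CD31-intensity-weighted
and sub-pixel. Gating computes each object's DAPI-overlap fraction
(share of its pixels inside the Otsu DAPI mask); `is_platelet` means
overlap < 0.1. Overlap-based gating is robust to nucleus/membrane
offset, unlike a centroid-in-nucleus test. Without a DAPI channel,
objects are returned ungated with a warning rather than silently
treated as platelets.

## Contact rule

"In contact" is not self-defining for centroid-to-pixel distances, so
the rule is explicit and configurable. Default: a platelet is in
contact with a tension class when its centroid distance to the nearest
class pixel is at most its own equivalent radius plus half a pixel — a
centroid within one radius of a target pixel means the object overlaps
it. A fixed tolerance (`contact_um`) is available instead; the
validation suite uses `contact_um = √2 · pixel` (one pixel diagonal),
the tightest rule consistent with pixel quantization, because it makes
the generator's seeded contact fraction exactly recoverable.

## The synthetic scene generator

The generator is the package's ground-truth instrument; its defaults
*are* the study conditions and are not tuned per analysis:

| parameter | default | meaning |
|---|---|---|
| `pixel_size_um` | 0.1 µm | Nyquist sampling of a 63× confocal |
| `image_shape` | 512 × 512 px | one 51 µm field of view |
| `n_fibers`, `fiber_length_px`, `fiber_width_px` | 30, 150, 2 | dilated random-walk polylines, ~15% fiber coverage |
| `untensed_fraction` (f) | 0.4 | target share of fiber pixels relaxed |
| `patchiness_um` | 2 µm | correlation scale of tension patches |
| `n_platelets`, `platelet_radius_um` | 50, 1 µm | anucleate CD31+ disks |
| `contact_fraction` (p) | 0.8 | platelets seeded on stretched pixels |
| `offset_distance_um` | 2 µm | exponential mean of non-contact offsets |
| `n_nucleated`, `nucleated_radius_um`, `nucleus_radius_um` | 10, 2 µm, 1.5 µm | lymphocyte-scale CD31+/DAPI+ cells |
| `snr`, `psf_sigma_px`, `background_level` | 10, 1 px, 200 | noise and blur |

Design decisions inside the generator, and why:

* **Tension labels are per-pixel, not per-fiber**: a Gaussian-smoothed
  random field (correlation scale `patchiness_um`) is thresholded at
  the empirical quantile of its values on fiber pixels, so labels form
  spatially coherent patches and the realized untensed fraction equals
  f to within one pixel's probability mass. Quantile calibration makes
  f a recoverable ground-truth parameter — the generator's main job.
* **Fiber density is calibrated to the offset law.** With dense fiber
  networks, no pixel lies far from a stretched fiber and large offsets
  are geometrically impossible; 30 fibers per 512² field leaves gap
  structure out to ~the 99th percentile of the exponential offset law,
  so the law is actually realizable.
* **Non-contact seeding is honest**: offsets are drawn from the
  exponential conditioned on exceeding one pixel diagonal (a seeded
  "non-contact" platelet is never itself in contact), and when spacing
  constraints reject a pixel, the *drawn distance is kept* and another
  pixel at that distance is tried — re-drawing under crowding would
  bias the realized offset law upward.
* **Spacing** keeps centroids at least max(2 platelet radii, sum of the
  pair's radii) apart; the second term prevents platelets from being
  swallowed by larger nucleated disks, which would merge detections.
  Nucleated cells are placed before platelets because uniform placement
  into an already platelet-crowded field fails rejection sampling.
* **Noise** is Poisson shot noise plus additive Gaussian read noise,
  scaled so the total noise s.d. at peak signal is `amplitude / snr`
  (each component contributes half the variance) — the standard
  fluorescence acquisition model. Output is 16-bit with declared
  saturation, matching common confocal export. `snr = Inf` and
  `psf_sigma_px = 0` give the exact noiseless limit used by boundary
  tests.

What the generator does **not** emulate — and what passing recovery
tests therefore do not show about real data: uneven illumination and
vignetting, autofluorescence structure, antibody penetration gradients,
true fiber bundling/branching morphology, out-of-focus light from
neighboring z-planes, chromatic registration error, platelet shape
irregularity, and biological correlation between fiber tension and cell
density beyond the planted contact coupling. Recovery results validate
the pipeline's correctness, not the biology of any particular tissue.

## Numerical choices

* **Otsu**: 256-bin histogram spanning the observed min–max (so the
  positive set is invariant under adding a constant); threshold is a
  bin edge; between-class variance computed from bin centers in double
  precision (cumulative class weights must be accumulated as doubles —
  pixel-count products overflow 32-bit integers on 512² images); ties
  broken toward the lowest split; an exact per-value mode
  (`n_bins = NULL`) for discrete data; constant input is an error, not
  a guess.
* **Ratio map**: scalar background subtraction (default 0; the
  simulator's scenes use their known background), numerator and
  denominator floored at 0, denominator floored at 10⁻⁶ of the 16-bit
  dynamic range to keep the map finite.
* **Distance transform**: exact Euclidean (verified against all-pairs
  brute force to 10⁻⁹ in the tests); distances sampled at sub-pixel
  centroids by bilinear interpolation (nearest-pixel by flag).
* **Determinism**: every stochastic step (scene generation, annotation
  sampling, forest training) takes an explicit seed; the generator
  derives its stage seeds from `SceneParams$seed` by fixed offsets, and
  pipeline reports exclude wall-clock and run-location strings so two
  runs of one config are byte-identical.
* **Coordinates**: (row, col) with pixel centers at integer positions,
  R's native 1-based indexing; physical distances are pixel distances
  times `pixel_size_um`.

## Validation problem sizes

The test suite validates by parameter recovery at desk scale: untensed
density across f ∈ {0.1, 0.25, 0.4, 0.6, 0.8} on 256² scenes (10 seeds
each, snr 10); contact fraction across p ∈ {0.2, 0.5, 0.8} on 512²
default scenes (10 seeds each), with the offset-law mean checked pooled
across the grid by matching detections to seeded non-contact platelets;
classifier floors on 256² scenes noisy and noiseless; gating on 512²
scenes; a 2,000-replicate null calibration of the statistical pathway
at n = 20 per group; and byte-level determinism of the pipeline on a
written fixture suite of 256² scenes spanning both grids.

## Known limitations

* The QuPath workflow being reconstructed is underspecified in several
  places (classifier features, cell-detection parameters, the contact
  notion, the normality-verdict rule); each gap is filled with an
  explicit, documented default rather than a guess at hidden intent,
  so absolute numbers can differ from the original MATLAB/QuPath
  outputs even where the science agrees.
* Analysis is strictly 2-D single-section; no z-stacks, registration,
  or whole-slide tiling.
* The exponential offset law is a modeling convenience — the real
  distance distribution of platelets to stretched fiber in tissue is
  unknown (only means are reported in the literature this emulates).
* Otsu thresholding is per-image; a cross-image shared threshold is not
  implemented beyond configuring `n_bins`/`background` identically,
  and batch effects between sections are out of scope.
* Distance-to-class statistics are sensitive to isolated
  misclassified pixels by construction (a single stray "stretched"
  pixel bounds the distance); the ratio classifier mitigates the
  dominant halo artifact, but very low SNR data will still need
  morphological cleanup upstream.
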