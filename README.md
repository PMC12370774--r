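# tensiomap

Quantifying the tensional state of fibronectin fibers in microthrombi
from multichannel immunofluorescence images.

## The problem

Fibronectin (Fn) fibers in the extracellular matrix can be mechanically
stretched (tensed) or relaxed (untensed). The bacterial-adhesin-derived
peptide probe FnBPA5 binds untensed fibronectin fibers with nM affinity
and loses binding when fibers are stretched, so a Cy5-FnBPA5 channel
imaged against a polyclonal total-fibronectin antibody channel reads out
fiber tension pixel by pixel. In microthrombi — the micron-scale
platelet/fibrin aggregates behind microthrombi-induced MINOCA — this
readout reveals heterogeneous patches of relaxed fiber inside the
thrombus stroma, and the spatial relationship between platelets
(CD31+/DAPI−) and fiber tension classes.

`tensiomap` implements that analysis as a tested, reusable R pipeline:

1. **Ratiometrics** — per-channel Otsu thresholds, the joint FN ∧ FnBPA5
   mask, the per-pixel ratio map `FNBPA5 / FN`, and the untensed-pixel
   density

   `density (%) = 100 · |FnBPA5+ ∧ FN+| / |FN+|`

2. **Tension classification** — a supervised random-forest pixel
   classifier over multiscale image features (plus two annotation-free
   threshold classifiers), partitioning the fiber mask into
   `untensed ∪ stretched`.
3. **Platelet detection & gating** — CD31 segmentation
   (smooth → Otsu → components → watershed), then DAPI-overlap gating of
   platelets versus nucleated cells.
4. **Proximity statistics** — exact Euclidean distance transforms of the
   two tension masks, sampled at platelet centroids:
   per-platelet distances `d_untensed`, `d_stretched` (µm), contact
   fractions and mean distances.
5. **Group statistics** — a four-test normality battery
   (D'Agostino–Pearson K², Anderson–Darling, Shapiro–Wilk,
   Lilliefors/KS; parametric iff ≥ 3 of 4 pass) gating an unpaired
   Student's t-test versus an exact/approximate Mann–Whitney test.
6. **Synthetic scenes** — a generator of ground-truthed multichannel
   images (fiber networks with patchy tension labels, platelets coupled
   to stretched fibers, nucleated cells, PSF blur, Poisson–Gaussian
   noise) that makes every stage testable by parameter recovery.

## Worked example

```r
library(tensiomap)

params <- scene_params(untensed_fraction = 0.4, contact_fraction = 0.8,
                       seed = 42)
scene  <- simulate_scene(params)
report <- run_pipeline(run_config(inputs = list(thrombus = scene$image),
                                  background = 200))
print(report)
```

```
RunReport (tensiomap 0.1.0): 1 image(s) analyzed, 0 failed
  thrombus: untensed density 38.7%, 50 platelets, contact 88% stretched / 28% untensed
  pooled: n = 50, contact 88.0% stretched / 28.0% untensed, mean d = 0.29 / 3.70 um
```

Reading the numbers: 38.7% of fibronectin-positive pixels are
tension-probe positive (the scene was generated with a 40% untensed
fraction); 50 CD31+/DAPI− platelets were detected and gated; 88% of them
are in contact with stretched fiber pixels but only 28% with untensed
ones (contact = centroid-to-pixel distance within the platelet's own
radius), and the mean centroid distance to stretched fiber is 0.29 µm
versus 3.70 µm to untensed fiber — platelets sit on the stretched
fibers, away from the relaxed patches.

Real images enter through `read_image()` (multi-page TIFF with a JSON
metadata sidecar, an explicit channel map, or per-channel grayscale
TIFFs; channels named FN, FNBPA5, CD31, DAPI). A thin command-line
wrapper with `simulate` / `ratiometric` / `run` / `compare` subcommands
is installed at `inst/cli/tensiomap.R`.

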