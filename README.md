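# vesselprox

Spatial statistics for cell-to-vessel coupling in 2D fluorescence
microscopy of developing bone (and any tissue where labeled cells
associate with a segmented vascular bed).

## The scientific problem

Osteoblast precursors co-invade the cartilage template with blood
vessels; how tightly they hug the endothelium is a readout of that
coupling. The measured quantity is, per labeled cell (e.g. an
Osterix-reporter-positive cell), the Euclidean distance to the nearest
vessel-positive pixel (e.g. an Endomucin mask) inside a region of
interest such as the primary ossification center. A shift of this
distance distribution between genotypes can be caused by three distinct
factors, and `vesselprox` implements the three Monte-Carlo controls that
dissect them:

* **repositioning null** — redistribute the observed cells uniformly at
  random over the extravascular ROI of their own vessel map (tests
  cell–vessel *attraction*);
* **matched-number null** — place the same chosen number of random cells
  on both maps (tests whether *cell number* explains the shift; i.i.d.
  placement means number alone never changes the distribution);
* **all-pixel distribution** — the exact distance law of every
  extravascular pixel of each map (tests whether *vessel morphology*
  alone explains the shift).

Comparisons use the exact two-sample Kolmogorov–Smirnov statistic with a
Monte-Carlo p-value, add-one corrected:
`p = (1 + #{D_r >= D_obs}) / (n_mc + 1)`. `attribute_shift()` runs all
three controls on a two-map contrast and names the factor(s) that
reproduce the observed shift. An explicit attraction model
`p(d) ∝ g(d)·[(1−α) + α·e^(−d/λ)/Z]` (with `g` the map's pixel distance
law) is fitted by maximum likelihood for parameter-recovery studies.

Around this core: exact Euclidean distance fields, vessel morphometry
(area fraction, exposed-edge perimeter-to-area ratio, 8-connected
components), looping-vessel counts within a configurable band (default
50 µm) of a junction polyline split into core/annulus, skeleton-based
tube-network metrics for co-culture assays, binned axial intensity
profiles with area normalization and background subtraction, and a
seeded synthetic microvasculature generator (correlated-random-walk
tubes, attraction-placed cells, intensity channels) that provides ground
truth for every stage.

## Worked example

```r
library(vesselprox)

cfg <- synthetic_config(shape = c(192, 192), n_tubes = 4, tube_radius = 6,
                        tube_steps = 30, tube_step = 8, n_cells = 300,
                        alpha = 0.7, lam = 15, roi_margin = 10, seed = 42)
scene <- generate_scene(cfg)

field <- compute_distance_field(scene$mask, scene$roi)
d     <- cell_distances(scene$cells, field, scene$mask)
summarize_distances(d)
#> proximity summary: n = 300 cells, mean = 19.19 um, sd = 13.84 um

pix <- null_all_pixels(field, scene$mask)
compare_distributions(d, pix, n_mc = 999, seed = 1)
#> KS = 0.1271, MC p = 0.002, mean diff = -4.43 um (n = 300)

fit_attraction(d, pix)
#> attraction fit: alpha = 0.660, lambda = 28.6 um, loglik = 14.32

vessel_morphometry(scene$mask, scene$roi)
#> vessel morphometry: area fraction 0.1219, perimeter 696.0 um, P/A 0.2458 1/um, 3 component(s)
```

Reading the output: the 300 synthetic cells sit on average 19.2 µm from
the nearest vessel. Against the repositioning null (whose exact
population is the all-pixel distance law), the observed distribution is
shifted toward the vessels (negative mean difference, −4.4 µm) and the
shift is significant (KS 0.127, Monte-Carlo p = 0.002) — correctly
detecting the attraction (`alpha = 0.7`) the generator planted. The
mixture fit recovers a substantial attraction weight; on a dense map
like this (area fraction 0.12) the length scale is only weakly
identified, which is why estimator validation uses sparser maps (see the
methods vignette). `run_pipeline()` stitches the per-sample analyses,
genotype aggregation, attribution, figures and a reproducibility
manifest together from a config list or YAML file.

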