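---
title: "Quantifying cell-to-vessel spatial coupling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell-to-vessel spatial coupling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselprox)
```

## The problem

In developing bone, osteoblast precursors invade the cartilage template
together with blood vessels, and their spatial association with the
endothelium is a readout of that coupling. The observable is simple: for
each labeled cell in a region of interest (e.g. the primary ossification
center), the Euclidean distance to the nearest vessel-positive pixel.
A between-condition shift in the distribution of these distances can,
however, have three quite different causes:

1. **attraction** — cells preferentially sit near vessels (or stop doing
   so);
2. **cell number** — fewer or more cells are present;
3. **vessel morphology** — the vascular bed itself is arranged
   differently, so even randomly placed cells would sit at different
   distances.

`vesselprox` implements the distance computation and three Monte-Carlo
controls that separate these factors, plus the supporting vessel
morphometry, looping-vessel band counts, axial intensity profiles, and a
synthetic microvasculature generator that provides ground truth for all
of it.

## Coordinate conventions

Rasters are isotropic with pixel size $s$ (µm per pixel); anisotropic
inputs are rejected. The centre of the 0-based pixel $(i, j)$ (row $i$,
column $j$) lies at physical coordinate $x = (j + 0.5)s$,
$y = (i + 0.5)s$; $x$ runs along columns, $y$ along rows. All external
files (cell CSVs, ROI polygons, junction polylines) are in µm; this
single pixel-centre rule converts between the two everywhere, so a
round trip µm → pixel → µm moves a point by at most $s/2$ in each
coordinate.

## Distances

`compute_distance_field()` assigns every pixel centre its exact
Euclidean distance to the nearest vessel-pixel centre (the distance
transform is exact, not chamfer-approximated; the test suite checks it
against an exhaustive min-over-all-vessel-pixels oracle at zero
tolerance). `cell_distances()` measures each cell from its *continuous*
µm coordinate to the nearest vessel-pixel centre by direct minimisation,
not by looking up the snapped pixel's field value, so sub-pixel cell
positions are respected exactly.

Two deliberate choices:

* Distances are centre-to-centre, not cell-to-vessel-boundary. The
  centre metric is exactly checkable against a brute-force oracle;
  boundary distances are available via
  `compute_distance_field(to_boundary = TRUE)` and differ appreciably
  only for wide vessels.
* Cells measure against vessel pixels on the **whole grid**, not only
  inside the ROI: a vessel just outside a manually drawn ROI boundary is
  still the biologically nearest vessel
  (`restrict_vessels_to_roi = TRUE` switches this off).

`summarize_distances()` reports the mean, the sample ($n-1$) standard
deviation, a histogram on uniform bins (default width 5 µm, starting at
0 — the conventional bin for this assay; configurable) and the
right-continuous ECDF.

## The three null models

All random placements are uniform over **extravascular ROI pixel
centres** (cells are extravascular by biology;
`allow_intravascular = TRUE` lifts this). Placing at pixel centres
rather than continuous positions is deliberate: it makes the
all-extravascular-pixel distribution (`null_all_pixels()`) the *exact*
population law of the other two nulls, which turns several tests into
exact identities rather than approximations.

* `null_reposition_observed()`: each replicate redistributes the
  observed number of cells uniformly at random over the extravascular
  ROI of their own map. Comparing the observed sample against this null
  tests attraction.
* `null_matched_number()`: the same construction with a caller-chosen
  common $n$, applied to both maps of a contrast. Because nearest-vessel
  distances of independently placed cells are i.i.d., cell number alone
  never changes the distance *distribution* — this null makes that
  explicit.
* `null_all_pixels()`: the deterministic distance distribution of every
  extravascular pixel; the morphology fingerprint of a map.

### Comparison statistic

The comparison procedure is this package's codification (the underlying
experimental controls are resampling constructions, so a resampling test
is the natural companion): the exact two-sample Kolmogorov–Smirnov
statistic against the null's pooled sample, with a Monte-Carlo p-value
from `n_mc` resamples of the observed sample size and the add-one rule
$p = (1 + \#\{D_r \ge D_{obs}\})/(n_{mc}+1)$, so the smallest attainable
p is $1/(n_{mc}+1)$. Defaults: `n_reps = 1000`, `n_mc = 999` (p
resolution 0.001). `n_mc < 19` is rejected outright. The mean
difference is reported alongside as an effect size in µm. The KS
evaluation handles ties exactly (distances live on a discrete pixel set)
and is computed in $O(n \log m)$ against a pre-sorted null, which is
what makes the calibration simulations cheap.

### Attribution verdict

`attribute_shift()` runs, for a two-map contrast: the attraction test in
each map, the between-map shift test on the observed samples (pooled
permutation null), and the morphology test — the two maps' exact pixel
distance populations, with the population KS judged against the
sampling noise of matched-number draws from the pooled population at the
observed cell count. The verdict column names every factor whose test
rejects at `alpha_level = 0.01`. The conservative level is deliberate:
three tests are read jointly, and at 0.01 the family-wise false-blame
rate stays low while the power of all three tests at realistic cell
counts (hundreds) is essentially unaffected. A contrast in which nothing
rejects but the sample sizes differ is reported as "no distribution
shift; samples differ only in cell number".

## The attraction estimator

For parameter-recovery testing the package also fits an explicit model.
With $g$ the map's extravascular pixel distance law, observed distances
are modelled as

$$p(d) \;=\; g(d)\left[(1-\alpha) + \alpha\,\frac{e^{-d/\lambda}}{Z(\lambda)}\right],
\qquad Z(\lambda) = E_g\!\left[e^{-d/\lambda}\right].$$

Because $g$ enters only as a constant factor, the log-likelihood reduces
to $\sum_i \log\!\big[(1-\alpha) + \alpha e^{-d_i/\lambda}/Z(\lambda)\big]$
with $Z$ a plain average over the pixel population — no density binning.
Optimisation is L-BFGS-B on $(\alpha, \log\lambda)$ with
$\alpha \in [0,1]$, $\lambda \in [0.5, 500]$ µm, from three starts
($\alpha_0 = 0.25, 0.5, 0.75$; $\lambda_0$ = median pixel distance);
non-convergence is flagged, not raised, and a degenerate (single-valued)
$g$ is reported as unidentifiable.

One parametrisation subtlety: the generator `place_cells()` samples
pixels with *unnormalised* kernel $(1-a) + a\,e^{-d/\lambda}$, so its
$a$ relates to the mixture weight by
$\alpha = aZ/(1-a+aZ)$. The fit reports both (`alpha` and the
back-converted `alpha_kernel`). $\lambda$ and the $\alpha = 0$ limit are
identical in both parametrisations.

Identifiability of $\lambda$ requires extravascular distances spanning
several $\lambda$: on dense vascular beds where most of the ROI lies
within one $\lambda$ of a vessel, the exponential is indistinguishable
from uniform and $\hat\lambda$ is noisy. Recovery experiments in the
test suite therefore use a sparse map (three thin tubes on a 256 px
grid, population mean distance ≈ 45 µm), where the median relative
error of $\hat\lambda$ at $a = 0.8$, $\lambda = 15$ µm, $n = 500$ is
well under 20%.

## Morphometry

* Vessel area, area fraction and components are integer pixel counts
  (components 8-connected; the complementary 4-connectivity is used for
  boundary edges, the standard pairing that avoids topological
  paradoxes).
* Perimeter is the count of exposed 4-edges times $s$. This is an exact,
  oracle-checkable integer computation whose known bias on smooth shapes
  (ratio → $4/\pi$ against the true perimeter of a disk as $s \to 0$;
  asserted in the tests) is *consistent* across conditions — and
  between-condition contrast is what the assay reports. The estimator
  name is recorded in the result object.
* Looping vessels: a component is counted when its minimum pixel-centre
  distance to the junction polyline is ≤ `band_width` (default 50 µm;
  centroid distance via `by_centroid = TRUE`). The band is split by
  junction arc length into a central core (default fraction 0.5) and
  flanking annulus — the split geometry is not canonical, so both the
  fraction and the estimator choice are parameters, and counts as well
  as per-mm² densities are emitted.
* Tube networks: Zhang–Suen thinning to a 1-px skeleton, segments traced
  between endpoint/junction nodes with geodesic length (1 or $\sqrt 2$
  steps), a minimum segment length of 10 µm to suppress spurs, counts
  normalised to ROI area in mm², and metrics relative to a matched
  control when given (a zero-tube control flags the ratios as
  undefined).

## Axial profiles

Each ROI pixel is assigned to the bin of its orthogonal (arc-length)
projection onto the axis; the per-bin value is
$\text{sum(bin intensities)}/\text{bin area} -
\text{sum(background)}/\text{background area}$,
i.e. mean intensity per µm² of the region in which the measurement was
taken, minus the identically normalised out-of-tissue background. The
default bin width is 25 µm (conventional range 20–30 µm). Three edge
rules: background ROIs must be disjoint from tissue; bins with zero
pixels are missing (`NA`), not zero; negative post-subtraction values
are preserved, because clamping at zero would bias between-condition
contrasts. Bin-order reversal invariance holds exactly when the axis
length is a whole number of bins (binning always starts at the axis
origin). `profile_features()` summarises a channel by its (leftmost)
argmax, a prominence, and the plateau run above a fraction of the
maximum.

## The synthetic generator

`generate_vessel_mask()` draws each vessel as a correlated random walk —
fixed step (default 10 µm), Normal(0, `turn_sd`) heading increments —
dilated to `tube_radius` by exact distance thresholding. Two parameters
(tube count and radius) are enough to emulate the relevant contrast:
a dense fine network versus a small number of larger vessels; tortuosity
is controlled separately by `turn_sd`. `place_cells()` samples
extravascular pixels with the attraction kernel above; $a = 0$ is
exactly the uniform null. `generate_scene()` adds an elliptical tissue
ROI, a junction polyline at 80% of the major axis (the distal end), and
two intensity channels — a mid-axis Gaussian bump (an "acute peak"
expression pattern) and a central plateau — over a constant
out-of-tissue background with additive Gaussian noise clipped at zero
(the simplest noise that exercises background subtraction). Everything
is a pure function of (config, seed); scene files regenerate
byte-for-byte.

Defaults model a fetal-bone field of view: 512 px grid at 1 µm/px, 12
tubes of 8 µm radius, 300 cells, attraction $a = 0.7$,
$\lambda = 15$ µm — the order of the wild-type mean nearest-vessel
distance in this assay. The tests run smaller grids (64–256 px) purely
as a problem-size choice; every property asserted is size-independent.

What the generator does *not* emulate: point-spread blur, segmentation
error, anisotropic voxels, vessel calibre gradients, and 3D topology.
Passing tests therefore validate the *analysis* — exact distances,
calibrated tests, correct attribution given correct masks — not the
upstream segmentation of real images.

## Reproducibility

Every stochastic operation takes a master seed; replicate $r$ derives
its own stream seed by a counter scheme (`derive_seed()`), so any single
replicate can be reproduced in isolation and identical (inputs,
parameters, seed) give identical outputs regardless of environment.
`run_pipeline()` writes a JSON manifest (inputs with MD5 checksums,
parameters, seed, package version, no timestamp) that is checksum-stable
across reruns.

## Known limitations

* 2D only; a 3D vascular bed projected to 2D overstates proximity.
* The pixel-centre distance metric ignores vessel width; use
  `to_boundary = TRUE` when calibre differs strongly between
  conditions.
* The attribution verdict is a codification — the underlying assay
  describes the three controls but not a formal decision rule — and is
  labelled as such in the output table attributes.
* Attribution compares one map per condition; multi-sample designs are
  aggregated per-sample first (`run_pipeline()` reports genotype
  mean ± SD across samples) and attribution is run on matched single
  samples.
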