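---
title: "Methods: microdroplet segmentation, survival statistics, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microdroplet segmentation, survival statistics, and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dropsurv` quantifies the microscopic wetness that persists on
bacteria-colonized surfaces drying under moderate relative humidity:
micrometre-scale droplets, pinned by cells and aggregates and stabilized by
deliquescent solutes, whose size strongly conditions the survival of the
cells inside them. This vignette is the package's own account of the
models, parameters and numerical choices behind each stage; nothing here
states a result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The image-analysis procedure

Input is one field of view as four registered 16-bit grayscale rasters:
bright field, green (live cells, constitutive YFP), red (dead cells,
propidium iodide) and a shorter-wavelength "blue" channel in which droplet
interiors fluoresce brighter than the background and the intensity falls
off steeply at the droplet rim.

**Droplets** (`segment_droplets()`). The blue channel is smoothed with a
Gaussian (`gaussian_sigma_px`, default 2 px), then two masks are formed:
pixels above an intensity threshold, and pixels above a threshold on the
Sobel gradient magnitude. Their union is taken, holes inside connected
components are filled, and components smaller than `min_droplet_area_um2`
are removed. The rationale for the union is that droplet centers are
brighter than both periphery and background (the intensity mask finds
interiors) while the gradient is most pronounced at the periphery (the
gradient mask closes faint rims so filling can complete the interior).
Thresholds are specified as tags — `otsu`, `quantile:q` or `fixed:v` — with
Otsu the default for intensity and the 90th percentile for the gradient
magnitude; with no published threshold values to adopt, parameter-free
defaults keep the synthetic validation honest, and every value can be
overridden.

**Cells** (`segment_cells()`). Green and red channels are thresholded
independently (default Otsu). A pixel above both thresholds is assigned to
the channel with the larger background-normalized intensity (intensity over
the channel median) — the classes are treated as exclusive, and this ratio
rule is the tie-break. Components below `min_cell_area_um2` (default
0.25 µm², about a quarter of a projected cell) are discarded so noise
speckle cannot enter the area statistics.

**Connectivity and labels.** All components are 8-connected. The labeling
routine runs a fast 4-connected pass and then merges labels that touch
diagonally via graph connected components; label images carry consecutive
ids from 1 and the pixel size.

**Quantification** (`label_aggregates()`, `assign_to_droplets()`,
`build_tables()`). A cellular object — solitary cell or aggregate — is one
8-connected component of the union of the live and dead masks. Each object
is assigned to the droplet with which it shares the most pixels; ties break
toward the smaller droplet id, and objects overlapping no droplet are kept
as "dry" so population totals are conserved. Areas are pixel counts times
the squared pixel size. A droplet's live/dead areas count the live/dead
pixels inside its own mask, whichever object they belong to: this makes
`cell_area ≤ droplet_area` hold by construction and gives an exact
conservation law (droplet totals plus dry totals equal the mask totals),
which the tests verify. The alternative reading — crediting protruding
pixels of an assigned object to its host droplet — would break both
properties; with well-separated objects the two readings coincide.

The analysis is deliberately 2-D: droplets and aggregates are treated
through their projected areas, assuming droplet area–volume monotonicity
and single-layered aggregates. No volumetric correction is attempted.

## Statistics

**Power-law exponent** (`fit_power_law()`). Droplet areas follow
p(A) ∝ A^γ with γ near −1, so the untruncated continuous power law is not
even normalizable and naive fits are improper. Two estimators are
provided:

* `truncated_mle`: maximum likelihood for the power law truncated to
  `[xmin, xmax]`, a 1-D likelihood maximization in γ, standard error from
  the observed information (numerical curvature at the optimum, step
  1e-4). With `xmax = Inf` (valid only for γ < −1) it reduces to the Hill
  estimator γ = −(1 + n/Σ log(xᵢ/xmin)), which the tests use as a closed-form
  oracle.
* `logbin_ls`: counts in logarithmically spaced bins converted to a
  density and fitted by least squares on log–log axes. This matches how
  such distributions are usually plotted and binned in published data, so
  it is the method of choice when comparing against published curves; the
  MLE is the statistically principled default for simulation work.

**Binned curves** (`binned_mean_curve()`). Summaries are binned on a log10
area scale; bin centers are geometric means of the edges; SEM is over the
individual observations in a bin. Empty bins are reported with `n = 0` and
`NA` mean — never dropped or interpolated — so curve alignment across
strains or conditions stays explicit. Default droplet bins are half-decades
over 1–10⁵ µm².

**Survival** (`survival_vs_droplet_size()`). Per-droplet survival is
live/(live+dead) area; droplets without cells are excluded. The default
curve averages droplets within each bin (each droplet is one observation,
SEM across droplets), which matches plots where each background dot is one
droplet; an area-pooled variant (`pooled = TRUE`) is available since the
two readings differ when droplet sizes are heterogeneous within a bin.
`overall_survival()` always pools.

**Contribution of droplet vs aggregate size** (`fit_contribution()`).
Whether survival is driven by the droplet or by the aggregate a cell sits
in is answered with a logistic regression of the per-object live/dead
outcome — events weighted by cell area — on *standardized* log10 droplet
area and log10 aggregate area, so the coefficient magnitudes are directly
comparable. With only two outcome classes a binomial model is the natural
form (fitted as quasibinomial to accommodate the non-integer area
weights). Perfect separation is detected by exploding coefficients and
flagged, and the model is refit with a small ridge penalty (`glmnet`,
alpha 0, lambda 1e-3). The two predictors are correlated by construction
(larger aggregates sit in larger droplets), so the model answers "which
carries more weight given the other", not a causal decomposition.

**Population curves.** `population_by_droplet_size()` sums live and dead
cell area per size bin (conserving the grand total);
`population_above_size()` reports the fraction of the cell-covered area
residing in droplets at least as large as each threshold, by default at 100
log-spaced thresholds from 10^1.5 µm² up to the largest droplet.

## Concentration estimation

Droplet solute concentrations are read off a calibration curve: mean
intensities of standards at known concentrations (the conventional
ten-point dilution series with factors 1.11–20), interpolated
piecewise-linearly (`build_calibration()`). Construction rejects
non-monotone intensity sequences, naming the offending knots, because a
non-monotone curve has no inverse. Droplet intensity
(`droplet_mean_intensity()`) is averaged after eroding the droplet mask by
a disc of radius ceil(1 µm / pixel size) — excluding the optically
distorted rim — and removing bead pixels. Intensities outside the knot
range are linearly extrapolated from the terminal segment and flagged
(`extrapolated = TRUE`) rather than clamped: real droplets can be more
concentrated than the densest standard, and silent saturation would hide
that. Between knots the curve is treated as exact; dye self-quenching at
high concentration is not modeled. An osmolarity helper multiplies the
factor by a user-supplied base osmolarity — no default base is shipped,
since it depends on the medium recipe and dissociation assumptions.

## The synthetic-scene generator

`sample_scene()` draws the latent truth; `render_channels()` rasterizes
it. Both are pure functions of the `scene_spec()`, so identical spec and
seed give bit-identical scenes and channels.

* **Droplet areas**: i.i.d. from the truncated power law via inverse-CDF
  sampling (exact and seedable). Defaults γ = −1.2 on [10, 10⁴] µm².
* **Placement**: droplet centers are placed by rejection sampling on a
  spatial grid hash with a 3 µm separation margin, so rendered droplets
  remain resolvable as distinct objects after blurring; in deliberately
  crowded draws the sampler falls back to overlapping placement rather
  than failing.
* **Coupling**: the cell-covered area inside a droplet of area A is
  `coupling_coeff`·A (default 0.12) with multiplicative lognormal noise
  (sd 0.4 on the log scale), clipped to at most `max_fill_fraction`
  (default 0.6) of A. The linear-with-noise form is a modeling choice: the
  underlying observation is only that droplet size increases with the
  cell mass inside, with no published functional form.
* **Aggregates**: one cellular object per droplet; the cell-covered area
  is split into cells of footprint 1 µm² packed single-layered in a disc
  (sunflower layout at packing density 0.55) around the droplet center.
  Solitary cells are simply aggregates of one inside correspondingly tiny
  droplets.
* **Survival**: each cell is live with probability
  s(A) = s_min + (s_max − s_min)·plogis(k·(log10 A − m)), defaults
  s_min = 0.02, s_max = 0.8, m = 3 (midpoint at 10³ µm²), k = 2.2. These
  reproduce the qualitative regime of interest: a few percent survival
  below 10² µm² rising to a majority above 10⁴ µm².
* **Rendering**: the blue channel paints each droplet as a plateau with a
  sigmoidal edge falloff whose half-maximum sits exactly at the true
  radius (so an intensity threshold midway between background and signal
  recovers the true area) plus a mild 10% radial dome making centers the
  brightest points; green/red paint hard-rasterized cell footprints; all
  channels get additive Gaussian noise, clipping to [0, 65535] and integer
  rounding. Pixel size defaults to 0.1625 µm/px (a 40x objective on a
  common sCMOS sensor) and is configurable.

What the generator does *not* emulate: irregular droplet outlines (circles
keep area ground truth exact), photon-limited (Poisson) noise, uneven
illumination, out-of-focus light, overlapping or multi-layered aggregates,
and autofluorescence. Passing the synthetic benchmarks therefore shows the
pipeline recovers truth under idealized optics with realistic additive
noise — not that it is robust to every artifact of real micrographs.

## The synthetic benchmark conditions

The segmentation benchmark (`benchmark_scene_spec()`,
`benchmark_seg_config()`) fixes: 332.8 × 332.8 µm fields at 0.325 µm/px
(1024² px), 40 droplets per field on [10, 3000] µm² (spanning 2.5 decades
while keeping tens of droplets per field), signal 20000 over background
2000 with noise sd 4000 — a signal-to-noise ratio of 5. The segmentation
settings were chosen once for this geometry: sigma 1 px, Otsu intensity
threshold, 99.5th-percentile gradient threshold (at the default 90th
percentile, the gradient mask's wide skirt inflates small-droplet areas),
minimum droplet area 5 µm² (half the smallest true droplet), and a fixed
cell threshold at half signal (11000): a histogram threshold drifts into
the noise tail on fields whose green or red channel contains almost no
true signal, inflating one class's area where the other dominates. The
acceptance suite runs 20 such fields end to end; module tests use 5–6
fields to stay fast. Statistical recovery tests that need no imaging
(exponent recovery, contribution model) run on 10,000-area draws and
3000–5000-object scenes sampled directly.

## Numerical choices and degenerate inputs

* Automatic thresholds on a constant image warn and return an empty mask
  instead of erroring: a blank field is a valid (if dull) observation.
* The MLE optimizer searches γ ∈ [−8, −1e-4] with `stats::optimize`
  (tol 1e-8); the γ = −1 log-uniform special case of the CDF and
  normalizer is handled explicitly (threshold |γ+1| < 1e-12).
* `fit_power_law` refuses fewer than 2 in-range areas or all-equal areas;
  log-binned fits require at least 2 occupied bins and report `NA`
  standard error with exactly 2 (zero residual degrees of freedom).
* Assignment ties (equal pixel overlap with two droplets) break toward the
  smaller droplet id, deterministically.
* Scene sampling and rendering consume disjoint RNG streams derived from
  the one spec seed (the render stream is offset by a fixed constant), so
  re-rendering a scene never perturbs the scene itself.
* Boundary erosion for intensity measurements rounds the ~1 µm exclusion
  *up* to whole pixels; a droplet with nothing left after erosion is an
  error ("too small to measure"), not a silent NA.

## Known limitations

* The pipeline quantifies areas, not cell counts; "survival" is an area
  ratio, a proxy that weights large cells more than small ones.
* Segmentation accuracy claims are backed by the synthetic benchmark only;
  real micrographs bring artifacts the generator does not model (above).
* The contribution model's coefficients inherit the collinearity of
  droplet and aggregate size; they rank the predictors, nothing more.
* With a single field of view, the size-distribution SEM is reported as 0
  in occupied bins (one replicate), so cross-field error bars require
  multiple 'repeat' values.
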