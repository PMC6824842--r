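# dropsurv

Quantifying microscopic surface wetness and bacterial survival on drying
surfaces.

When a bacteria-colonized surface dries under moderate relative humidity,
the receding liquid film is pinned by cells and aggregates, and deliquescent
solutes keep the pinned residues from evaporating completely. The result is
a stable landscape of micrometre-sized droplets — large ones around
aggregates, minuscule ones around solitary cells — and cell fate depends on
that landscape: survival climbs steeply with the area of the droplet a cell
ends up in. `dropsurv` implements the full image-analysis and statistical
pipeline for this kind of experiment, plus a seeded synthetic-scene
generator so every stage can be validated against known ground truth
without access to the original micrographs.

## What it computes

The pipeline consumes four registered 16-bit grayscale channels per field
of view — bright field, green (live, YFP), red (dead, propidium iodide) and
a blue channel that highlights the droplets — and produces:

* **Droplet masks** from the blue channel: Gaussian smoothing, then the
  union of an intensity mask (droplet interiors are brighter than
  background) and a gradient-magnitude mask (the gradient peaks at the
  droplet periphery), hole filling, small-object removal
  (`segment_droplets()`).
* **Live/dead cell masks** by per-channel histogram thresholds with a
  ratio rule for ambiguous pixels (`segment_cells()`).
* **Records**: cellular objects (8-connected components of the cell mask)
  assigned to their host droplet by maximal pixel overlap; per-droplet and
  per-object areas in µm² (`label_aggregates()`, `assign_to_droplets()`,
  `build_tables()`).
* **Statistics**: droplet-area power law p(A) ∝ A^γ fitted by truncated
  maximum likelihood or log-binned least squares (`fit_power_law()`);
  log-binned mean ± SEM curves; survival s = live/(live+dead) versus
  droplet size; live/dead population distributions; survival over droplet
  size × aggregate size; an area-weighted logistic regression that compares
  the standardized contributions of droplet and aggregate size to survival
  (`fit_contribution()`); the fraction of the population residing above a
  droplet size; overall pooled survival.
* **Concentration estimates** from a dye channel via monotone
  piecewise-linear calibration curves, with a ~1 µm boundary ring and bead
  pixels excluded from droplet intensities (`build_calibration()`,
  `droplet_mean_intensity()`, `estimate_concentration()`).

The generator (`scene_spec()`, `sample_scene()`, `render_channels()`) draws
droplet areas from a truncated power law (exponent γ, default −1.2 on
[10, 10⁴] µm²), couples cell-covered area to droplet area, labels each cell
live with probability
s(A) = s_min + (s_max − s_min)·logistic(k·(log10 A − m)), and renders all
four channels with additive Gaussian noise — deterministically from one
seed.

## Worked example

```r
library(dropsurv)

spec   <- benchmark_scene_spec(seed = 7)        # 333 x 333 um, SNR 5
scene  <- sample_scene(spec)                    # latent ground truth
stack  <- render_channels(scene, spec, "demo")  # 16-bit channels
px     <- stack$pixel_size_um

droplets <- segment_droplets(stack$blue, benchmark_seg_config(), px)
cells    <- segment_cells(stack$green, stack$red, benchmark_seg_config(), px)
objects  <- label_aggregates(cells$live, cells$dead, px)
hosts    <- assign_to_droplets(objects, droplets)
tabs     <- build_tables(droplets, objects, cells$live, cells$dead,
                         hosts, px, "demo")

fit_power_law(tabs$droplets$area_um2, "truncated_mle", xmin = 10)
#> Power-law fit (truncated_mle): gamma = -1.174 +/- 0.099  [10, 2898.35], n = 40

surv <- survival_vs_droplet_size(tabs$droplets,
                                 bin_spec(lo = 10, hi = 3000, n = 5))
surv[surv$n > 0, c("bin_center", "mean", "sem", "n")]
#>   bin_center  mean   sem  n
#> 1         18 0.000 0.000 13
#> 2         55 0.036 0.020 11
#> 3        173 0.101 0.051  4
#> 4        542 0.361 0.052  5
#> 5       1696 0.585 0.017  7

overall_survival(tabs$droplets)   # 0.51
```

All 40 generated droplets are recovered as 40 labels; the fitted exponent
matches the generator's γ = −1.2 within its standard error, and survival
rises from 0 in the smallest droplets to ~0.6 in the largest — the
generator's logistic made visible through the full imaging pipeline.

The `analysis/` scripts run the same workflow as a narrative study —
`01_simulate_fields.R` through `05_concentration.R` — writing tables under
`results/`.

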