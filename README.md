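# dhmwound

Quantitative phase imaging analysis of epithelial wound healing with
digital holographic microscopy (DHM).

In vitro wound assays follow the closure of a cell-free gap in an
epithelial monolayer. DHM records off-axis holograms from which a
quantitative phase image `Δφ(x, y)` (radians of optical path-length
delay) is reconstructed — no staining, no phototoxic labels, repeatable
every few minutes for days. Because the phase delay of a transparent
cell is

```
Δφ = (2π/λ) (n_cell − n_medium) d
```

(`d` thickness, `n_cell` the integral cellular refractive index,
`n_medium` the medium index, `λ` the wavelength), one time-lapse yields
simultaneously:

- the cell-covered area `S_c` (image segmentation),
- the dry mass in the wound, `DM = λ/(2πα) · Σ Δφ_i · A_pixel`, with
  `α ≈ 2×10⁻⁴ m³/kg` the protein refractive increment,
- the mean layer thickness `d̄ = λ Δφ̄ / (2π (n_cell − n_medium))`,
- the layer volume `V = S_c · d̄`, linked exactly by
  `DM = (n_cell − n_medium) V / α`,
- a cell-number estimate, `ΔDM / DM_single_cell`,

and per-minute rate constants for each by linear regression. The
single-cell inputs (`n_cell`, `DM_single_cell`) come from fitting the
spherical-cell phase model
`Δφ(ρ) = (4π/λ)(n_cell − n_medium)√(r² − ρ²)` to suspended cells.

The package covers the whole chain: off-axis hologram simulation,
Fourier sideband demodulation, least-squares 2-D phase unwrapping,
polynomial background flattening, sphere fitting, segmentation,
wound-assay metrics and rates, plus a synthetic-data generator with
planted ground truth for every stage. See the vignette
(`vignettes/dhm-wound-quantification.Rmd`) for the model details and
design choices.

## Worked example

Fit a noisy suspended cell and recover a wound-closure rate:

```r
library(dhmwound)

# -- single suspended cell -------------------------------------------
cfg <- optical_config(pixel_pitch_um = 0.25)     # 532 nm, n_medium 1.339
img <- make_sphere_image(radius_um = 9.1, n_cell = 1.3707, cfg,
                         noise_sd = 0.05, seed = 42)
fit_sphere(img, cfg)
#> Sphere fit: r = 9.101 um, n_cell = 1.37068, V = 3157.8 um^3,
#>             DM = 500.3 pg (rmse 0.05008 rad, 8464 px)

# -- wound assay: one front advancing 0.21 um/min --------------------
cfg2 <- optical_config(pixel_pitch_um = 0.5)
spec <- assay_spec(field_um = c(750, 110), gap_start_um = 100,
                   gap_end_um = 700,
                   front_speed = c(left = 0.21, right = 0), n_frames = 81)
assay <- make_wound_assay(spec, cfg2)
cov <- gap_coverage_series(assay$stack, assay$geometry)
estimate_rates(cov, metrics = "S_c_um2")
#>    metric slope          se   units n_frames n_replicates
#> 1 S_c_um2  23.1 0.002510213 um2/min       81            1
```

The fitted radius (9.101 µm) and index (1.37068) recover the planted
values under 0.05 rad phase noise; the fit's dry mass follows from
`(n_cell − n_medium)·(4/3)πr³/α`. The recovered area rate, 23.1 µm²/min,
is exactly the planted front speed times the band height
(0.21 µm/min × 110 µm): per-frame rasterization quantizes areas to
whole pixel columns, but the regression slope is unbiased.

`run_pipeline()` ties the stages together from a YAML configuration
(see `inst/extdata/example_config.yaml`), reading TIFF stacks of phase
maps or raw holograms and writing tidy `metrics.csv` / `rates.csv` with
unit-bearing columns. `inst/scripts/dhm-pipeline.R` exposes the same
functions as a small command line
(`simulate-spheres`, `simulate-assay`, `reconstruct`, `fit-spheres`,
`analyze`).

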