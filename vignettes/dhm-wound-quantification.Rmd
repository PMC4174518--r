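---
title: "Quantifying epithelial wound healing from digital holographic microscopy"
author: "dhmwound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying epithelial wound healing from digital holographic microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhmwound)
```

## The measurement problem

In vitro wound (scratch/insert) assays follow the closure of a cell-free
gap in an epithelial monolayer, classically by staining cells and
counting them at a few time points. Digital holographic microscopy (DHM)
replaces staining with interferometry: an off-axis hologram encodes the
full complex object wave, and its demodulation yields a quantitative
phase image — a 2-D map of the optical path-length delay `Δφ(x, y)` in
radians. Because that delay is proportional to the product of cell
thickness and refractive-index contrast, a single stain-free time-lapse
supports several read-outs at once: the cell-covered area, the dry
(non-aqueous, chiefly protein) mass in the wound, the mean layer
thickness and the layer volume, and from these an estimate of the number
of cells that migrated or grew into the gap.

`dhmwound` implements this chain end-to-end, from simulated raw
holograms to per-minute rate constants, together with a synthetic-data
generator that plants known ground truth for every stage.

## Governing relations

Three closed forms connect phase to morphology. For a cell of thickness
`d` and integral refractive index `n_cell` in medium `n_medium` at
wavelength `λ`:

* phase contrast: `Δφ = (2π/λ) (n_cell − n_medium) d`
  (`phase_from_thickness()`);
* dry mass over a region, via the refractive increment `α`:
  `DM = λ/(2πα) · Σ_pixels Δφ_i · A_pixel` (`dry_mass()`);
* mean thickness over a region, inverting the first relation on the
  region-mean phase: `d̄ = λ Δφ̄ / (2π (n_cell − n_medium))`
  (`mean_thickness()`).

Multiplying covered area by mean thickness gives the layer volume, and
the three quantities are algebraically locked together:
`DM = (n_cell − n_medium) V / α` holds for every frame because both
sides reduce to the same integrated phase. The package asserts this
identity at machine precision; it is a useful internal-consistency check
for any quantitative phase pipeline.

### The refractive increment

`α` converts integrated optical density into mass; for protein it is
close to 0.2 mL/g, i.e. `2 × 10⁻⁴ m³/kg`. Published applications of
this method occasionally print the value with a slipped decimal or unit
(`0.002 m³/kg`), which is ten-fold inconsistent with the dry masses
derived from it: with the conventional `2 × 10⁻⁴ m³/kg`, a suspended
epithelial cell of volume 3445 µm³ and index 1.3707 in medium 1.339
weighs `(n_cell − n_medium)·V/α ≈ 546 pg`, squarely inside the reported
range for such cells, whereas the slipped value would give 55 pg. The
package therefore defaults to `alpha_m3_per_kg = 2e-4` and keeps the
parameter configurable in `optical_config()`.

### Units

Internally: µm for length, radians for phase, pg for mass, minutes for
time. `optical_config()` performs the single conversion
`1 m³/kg = 1000 µm³/pg` once; everything downstream is unit-stable, and
all output columns carry unit-bearing names (`S_c_um2`,
`slope_pg_per_min`-style `units` fields).

## From hologram to phase

`simulate_hologram()` models the off-axis geometry: a plane reference
wave tilted to carry spatial frequency `(f_x, f_y)` (cycles/pixel)
interferes with the object wave, giving
`I = |O|² + |R|² + 2|O||R| cos(2π(f_x x + f_y y) + Δφ)`. The carrier
must stay strictly below the Nyquist limit of 0.5 cycles/pixel or the
sidebands alias.

`reconstruct_phase()` demodulates by multiplying with
`exp(−2πi(f_x x + f_y y))` — which shifts the `+` sideband to zero
frequency — and low-pass filtering in the Fourier domain before taking
the argument of the inverse transform. The spectral window is a
flat-core raised cosine (Tukey) of radius 0.8 × |carrier| with the flat
core at half the radius. A narrower window (half the carrier magnitude)
is a common default but measurably truncates the spectrum of
sharp-edged objects: on a planted spherical cell the round-trip RMSE
drops from 0.064 rad to 0.042 rad when widening to 0.8 × |carrier|,
while the window still vanishes before the autocorrelation terms at the
carrier distance. The radius is a `window_radius` argument when a
different trade-off is wanted. If no carrier is supplied the spectral
peak is detected, refined below bin resolution from the mean residual
phase gradient of a first demodulation pass, and the demodulation is
repeated; undetectable carriers (no off-origin peak above a prominence
threshold) raise an error rather than returning noise.

`unwrap_phase()` removes the 2π ambiguity with a least-squares
(Poisson) unwrapper: the discrete Laplacian of the wrapped phase
gradients is integrated under Neumann boundary conditions via a
mirror-extended FFT, and the smooth least-squares surface is then
rounded back onto the congruence lattice of the wrapped input. On clean
fields this recovers planted ramps and sphere caps to machine
precision; under noise it degrades gracefully instead of streaking. The
zero level is anchored by shifting the minimum over a designated
background region (default: the whole image) to zero.

`background_correct()` fits a low-order 2-D polynomial (default: a tilt
plane) to a cell-free region and subtracts it, which is a precondition
for the dry-mass and thickness formulas: cell-free pixels must sit at
zero phase.

Numerical caveats worth knowing:

* All round-trip accuracy statements exclude an 8-pixel border, where
  the periodic FFT assumption leaks.
* Spectral ringing at a step edge scales with the step height. A 2 µm
  plateau (≈ 0.76 rad) round-trips below 0.05 rad whole-frame RMSE; a
  5 µm plateau does not, although its interior is still recovered to
  ≈ 0.01 rad. Whole-frame RMSE bounds are therefore quoted for smooth
  fields, and plateau-interior accuracy for confluent layers.

## Suspended single cells: the sphere fit

Detached, suspended epithelial cells are near-spherical, so their
thickness profile is `d(ρ) = 2√(r² − ρ²)` and their phase footprint
peaks at `(4π/λ)(n_cell − n_medium) r`. `fit_sphere()` recovers
`(centre, r, n_cell)` by nonlinear least squares (Levenberg–Marquardt,
`minpack.lm`) against this model and derives volume `(4/3)πr³` and dry
mass `(n_cell − n_medium)V/α` from the fit. Radius and index are
separately identifiable — the footprint pins the radius, the amplitude
the index — which the tests confirm by doubling the planted contrast
and observing an unchanged fitted radius.

Initialisation is deterministic (no random restarts): centre from the
phase-weighted centroid of the pixels above a 0.5 rad blob threshold,
radius from the equivalent-area circle of that blob, index from the
peak phase via the closed form. The fitting window is the blob bounding
box dilated by 25%; background pixels inside the window anchor the
model's zero level. An image whose maximum phase stays below the blob
threshold is reported as "no blob" rather than fitted.

`batch_fit()` maps the fit over a stack, excludes and counts failures,
and reports per-parameter means with standard errors (`SD/√n`; a single
cell yields `NA`). Population inputs for validation come from
`make_sphere_population()`, which draws radius and index from truncated
normals. Defaults mirror an untreated epithelial control population of
89 cells with radius 7.2 ± 1.2 µm (population SD) and index
1.3713 ± 0.0006 (standard error at n = 89; the generator converts this
to a population SD of `0.0006·√89 ≈ 0.0057`). Reported "±" values for
radii are treated as population SDs and "± SE" values as standard
errors of the mean; the two must not be conflated when planting
populations.

## Wound assays: segmentation and kinetics

`segment_cells()` replaces interactive segmentation tools with a small
documented scheme: optional Gaussian pre-smoothing (σ = 1 px),
thresholding, morphological closing with a 3-px disc, removal of
components below 50 µm² and filling of interior holes below 50 µm²
(all configurable; EBImage supplies the morphology). The `"auto"`
threshold is Otsu's method on the phase histogram clipped at zero,
floored at three times the robust (MAD) background noise level so an
empty noisy frame yields an empty mask rather than a noise mask. This
is not a reproduction of any particular interactive pipeline — the
procedure, not specific area values, is the contract.

`gap_coverage_series()` restricts the mask to a fixed wound geometry
(an axis-aligned band or a polygon, `wound_geometry()`) and reports the
covered area per frame plus its change against frame 0 — pure
bookkeeping, no smoothing. Pixel-centre rasterization quantizes any
single frame's area to whole pixel columns (a bias of up to one pixel
column per front edge); differential quantities — per-frame gains and
regression slopes — are free of that constant bias, which is why rate
constants recover planted front speeds to well under 1%.

`compute_frame_metrics()` evaluates the three governing relations per
frame; `relative_series()` subtracts the first frame from area and dry
mass (thickness and volume stay absolute); `estimate_cell_number()`
divides accumulated dry mass by the mean single-cell dry mass of the
same condition, so the count starts at zero and tracks cells *added* to
the wound; and `estimate_rates()` fits ordinary least squares against
time. With replicate series, replicates are averaged per time point
first and the regression runs on the averaged series; the reported SE
is the regression standard error of the averaged fit (a per-replicate
regression is available by calling `estimate_rates()` per replicate,
but averaging-then-regressing is the default). Thickness slopes are
reported in nm/min — the natural magnitude for epithelial layers, whose
thickening rates are fractions of a nanometre per minute.

`thickness_profile()` converts phase to thickness pixel-wise and
averages along one axis within a band, tracing the layer profile across
the wound.

## The synthetic generator

`make_wound_assay()` plants piecewise-linear dynamics: two confluent
plateaus whose inner fronts advance into the gap at constant speeds
(negative speeds retreat) while their thicknesses change at constant
rates, with optional sinusoidal front roughness and iid Gaussian phase
noise. Linearity is the observed regime of insert-based assays over
tens of hours, and it makes the ground truth exact: per-frame covered
area, thickness, volume and dry mass are computed in closed form and
returned alongside the stack. Defaults mirror the standard experiment:
a 500 µm insert gap imaged every 30 min for 40 h (81 frames), layer
index 1.3713, noise 0.05 rad.

What the generator does *not* emulate — and what passing tests
therefore cannot certify about real data: subcellular phase texture
(organelles, membrane ruffles), spatially correlated noise and fixed-
pattern artefacts, heterogeneous per-cell motility, mitotic rounding,
and out-of-focus blur. Recovery results on these synthetics validate
the algebra, the demodulation chain and the estimators, not the
segmentation's robustness to biological texture.

Determinism is contractual: every stochastic element flows through a
seed stored in the spec, identical specs give bit-identical stacks, and
a full `run_pipeline()` with a fixed configuration writes byte-identical
CSVs.

## Problem sizes and tolerances

The validation suite runs, by choice, at moderate sizes: sphere fits on
≈ 150–190 px square fields at 0.25–0.5 µm pitch, hologram round trips
on 96–256 px fields, a population of 89 cells at 0.5 µm pitch, and the
full 81-frame assay at 0.5 µm pitch (1500 × 220 px frames) for the
area-rate recovery. Key tolerances: fitted radius and index on
noise-free spheres to < 0.1% relative; hologram round-trip RMSE
< 0.05 rad on smooth fields beyond an 8-px border; segmented coverage
within 2% of planted coverage across 10–90% fill; recovered area rate
within 2% of the planted front-speed × band-height product; the
frame-wise mass–volume identity at machine precision.

## Limitations

* The sphere fit assumes one dominant compact blob; it does not select
  cells by morphology, split touching cells, or refocus defocused ones.
* Connected-component labelling merges touching cells; no watershed or
  tracking is attempted (confluent epithelia defeat reliable per-cell
  tracking in this modality).
* The layer metrics assume a single effective refractive index per
  condition region, taken from suspended-cell fits of that condition;
  intra-layer index gradients are absorbed into the thickness estimate.
* Amplitude/absorption contrast, dispersion of the refractive
  increment, and aberrations beyond low-order polynomials are out of
  scope.
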