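#' Optical configuration for quantitative phase imaging
#'
#' Bundles the quantities shared by every conversion between phase,
#' thickness, refractive index, volume and dry mass: the laser wavelength,
#' the refractive index of the culture medium, the refractive increment
#' relating solute concentration to refractive index, and the object-space
#' pixel pitch.
#'
#' Internally all lengths are micrometres, phase is radians, mass is
#' picograms and time is minutes. The refractive increment is accepted in
#' m^3/kg (the conventional protein value is about 2e-4 m^3/kg, i.e.
#' 0.2 mL/g) and converted once to um^3/pg (1 m^3/kg = 1000 um^3/pg).
#'
#' @param wavelength_nm laser wavelength in nanometres; default 532.
#' @param n_medium refractive index of the culture medium; default 1.339.
#' @param alpha_m3_per_kg refractive increment in m^3/kg; default 2e-4.
#' @param pixel_pitch_um object-space pixel pitch in micrometres;
#'   default 0.5.
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config()
#' phase_from_thickness(10, 1.3713, cfg)
#' @export
optical_config <- function(wavelength_nm = 532, n_medium = 1.339,
                           alpha_m3_per_kg = 2e-4, pixel_pitch_um = 0.5) {
  check_scalar(wavelength_nm, "wavelength_nm")
  check_scalar(n_medium, "n_medium")
  check_scalar(alpha_m3_per_kg, "alpha_m3_per_kg")
  check_scalar(pixel_pitch_um, "pixel_pitch_um")
  if (wavelength_nm <= 0) stop_units("wavelength_nm must be > 0 (nanometres)")
  if (pixel_pitch_um <= 0) stop_units("pixel_pitch_um must be > 0 (micrometres)")
  if (n_medium <= 1.0 || n_medium >= 1.5) {
    stop_units("n_medium must lie in (1.0, 1.5); got ", n_medium)
  }
  if (alpha_m3_per_kg <= 0) {
    stop_units("alpha_m3_per_kg (refractive increment) must be > 0")
  }
  structure(
    list(
      wavelength_nm = wavelength_nm,
      wavelength_um = wavelength_nm / 1000,
      n_medium = n_medium,
      alpha_m3_per_kg = alpha_m3_per_kg,
      # 1 m^3/kg = 1e18 um^3 / 1e15 pg = 1000 um^3/pg
      alpha_um3_per_pg = alpha_m3_per_kg * 1000,
      pixel_pitch_um = pixel_pitch_um
    ),
    class = "optical_config"
  )
}

#' @export
print.optical_config <- function(x, ...) {
  cat("Optical configuration\n")
  cat(sprintf("  wavelength:          %g nm\n", x$wavelength_nm))
  cat(sprintf("  medium index:        %g\n", x$n_medium))
  cat(sprintf("  refractive increment: %g m^3/kg (%g um^3/pg)\n",
              x$alpha_m3_per_kg, x$alpha_um3_per_pg))
  cat(sprintf("  pixel pitch:         %g um\n", x$pixel_pitch_um))
  invisible(x)
}

#' Quantitative phase image
#'
#' A 2-D map of optical phase delay in radians with its object-space pixel
#' pitch and an optional acquisition time. This is the central data
#' currency of the pipeline: holograms demodulate into phase images, and
#' every morphometric quantity (dry mass, thickness, volume) is computed
#' from them.
#'
#' @param values numeric matrix of phase values (radians); must be finite.
#' @param pixel_pitch_um object-space pixel pitch in micrometres.
#' @param time_min acquisition time in minutes since assay start, or `NA`.
#' @return An object of class `phase_image`.
#' @export
phase_image <- function(values, pixel_pitch_um, time_min = NA_real_) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_units("phase values must be a numeric matrix (radians)")
  }
  if (any(!is.finite(values))) {
    stop_units("phase values must all be finite (radians)")
  }
  check_scalar(pixel_pitch_um, "pixel_pitch_um")
  if (pixel_pitch_um <= 0) stop_units("pixel_pitch_um must be > 0")
  structure(
    list(values = values, pixel_pitch_um = pixel_pitch_um,
         time_min = as.numeric(time_min)),
    class = "phase_image"
  )
}

#' @export
print.phase_image <- function(x, ...) {
  cat(sprintf("Phase image %d x %d px (pitch %g um)%s; range [%.3g, %.3g] rad\n",
              nrow(x$values), ncol(x$values), x$pixel_pitch_um,
              if (is.na(x$time_min)) "" else sprintf(", t = %g min", x$time_min),
              min(x$values), max(x$values)))
  invisible(x)
}

# Check that an image's pitch matches the configuration it is analysed with.
check_pitch <- function(img, cfg) {
  if (!isTRUE(all.equal(img$pixel_pitch_um, cfg$pixel_pitch_um))) {
    stop_units(sprintf(
      "pixel pitch mismatch: image %g um vs config %g um",
      img$pixel_pitch_um, cfg$pixel_pitch_um))
  }
  invisible(TRUE)
}

check_mask <- function(mask, img, require_nonempty = TRUE) {
  if (!is.logical(mask) || !is.matrix(mask)) {
    stop_units("mask must be a logical matrix")
  }
  if (!identical(dim(mask), dim(img$values))) {
    stop_units("mask shape ", paste(dim(mask), collapse = "x"),
               " does not match image shape ",
               paste(dim(img$values), collapse = "x"))
  }
  if (require_nonempty && !any(mask)) stop_units("mask is empty")
  invisible(TRUE)
}

#' Area of a region mask
#'
#' @param mask logical matrix marking the region.
#' @param pixel_pitch_um pixel pitch in micrometres.
#' @return Area in square micrometres (pixel count times pitch squared).
#' @export
mask_area <- function(mask, pixel_pitch_um) {
  if (!is.logical(mask)) stop_units("mask must be logical")
  check_scalar(pixel_pitch_um, "pixel_pitch_um")
  sum(mask) * pixel_pitch_um^2
}

#' Phase contrast of a cell of given thickness
#'
#' The phase delay induced by a transparent object of thickness `d_um` and
#' integral refractive index `n_cell` immersed in a medium of index
#' `n_medium` at wavelength `lambda` is
#' `Delta_phi = (2*pi/lambda) * (n_cell - n_medium) * d`.
#'
#' @param d_um cell thickness in micrometres (scalar or array), `>= 0`.
#' @param n_cell integral cellular refractive index, `>= n_medium`.
#' @param cfg an [optical_config()].
#' @return Phase in radians, same shape as `d_um`.
#' @export
phase_from_thickness <- function(d_um, n_cell, cfg) {
  stopifnot(inherits(cfg, "optical_config"))
  if (any(!is.finite(d_um))) {
    stop_units("thickness d_um must be finite (micrometres)")
  }
  if (any(d_um < 0)) {
    stop_units("thickness d_um must be >= 0 micrometres; got min ",
               min(d_um))
  }
  check_scalar(n_cell, "n_cell")
  if (n_cell < cfg$n_medium) {
    stop_units("n_cell (", n_cell, ") must be >= n_medium (", cfg$n_medium,
               "): a cell less dense than the medium has negative contrast")
  }
  (2 * pi / cfg$wavelength_um) * (n_cell - cfg$n_medium) * d_um
}

#' Mean cell thickness over a region from mean phase
#'
#' Inverts the phase/thickness relation for the region average:
#' `d_mean = lambda * mean(Delta_phi) / (2*pi*(n_cell - n_medium))`.
#'
#' @param img a [phase_image()], background-corrected so cell-free pixels
#'   sit near zero.
#' @param mask logical matrix selecting the cell-covered region; non-empty.
#' @param n_cell integral cellular refractive index, `> n_medium`.
#' @param cfg an [optical_config()].
#' @return Mean thickness in micrometres.
#' @export
mean_thickness <- function(img, mask, n_cell, cfg) {
  stopifnot(inherits(img, "phase_image"), inherits(cfg, "optical_config"))
  check_pitch(img, cfg)
  check_mask(mask, img)
  check_scalar(n_cell, "n_cell")
  if (n_cell <= cfg$n_medium) {
    stop_units("degenerate contrast: n_cell (", n_cell,
               ") must exceed n_medium (", cfg$n_medium,
               ") to convert phase to thickness")
  }
  mphi <- mean(img$values[mask])
  cfg$wavelength_um * mphi / (2 * pi * (n_cell - cfg$n_medium))
}

#' Cellular dry mass from integrated phase
#'
#' The dry (non-aqueous, chiefly protein) mass in a region follows from
#' the integrated phase via the refractive increment `alpha`:
#' `DM = (lambda / (2*pi*alpha)) * sum(Delta_phi_i) * pixel_area`.
#' The result is additive over disjoint masks.
#'
#' @inheritParams mean_thickness
#' @return Dry mass in picograms.
#' @export
dry_mass <- function(img, mask, cfg) {
  stopifnot(inherits(img, "phase_image"), inherits(cfg, "optical_config"))
  check_pitch(img, cfg)
  check_mask(mask, img)
  pix_area <- cfg$pixel_pitch_um^2
  (cfg$wavelength_um / (2 * pi * cfg$alpha_um3_per_pg)) *
    sum(img$values[mask]) * pix_area
}

#' Dry mass of a volume of known refractive index
#'
#' Integrating the phase/thickness relation over a cell of volume `V`
#' gives the closed form `DM = (n_cell - n_medium) * V / alpha`,
#' independent of shape. With the default increment of 2e-4 m^3/kg this is
#' 5 pg per unit of `Delta_n * V` in um^3.
#'
#' @param volume_um3 volume in cubic micrometres, `>= 0`.
#' @param n_cell integral refractive index.
#' @param cfg an [optical_config()].
#' @return Dry mass in picograms.
#' @export
sphere_dry_mass <- function(volume_um3, n_cell, cfg) {
  stopifnot(inherits(cfg, "optical_config"))
  if (any(!is.finite(volume_um3)) || any(volume_um3 < 0)) {
    stop_units("volume_um3 must be finite and >= 0 (cubic micrometres)")
  }
  check_scalar(n_cell, "n_cell")
  (n_cell - cfg$n_medium) * volume_um3 / cfg$alpha_um3_per_pg
}

#' Cell layer volume from covered area and mean thickness
#'
#' @param s_c_um2 cell-covered area in square micrometres, `>= 0`.
#' @param d_mean_um mean thickness in micrometres, `>= 0`.
#' @return Volume in cubic micrometres.
#' @export
layer_volume <- function(s_c_um2, d_mean_um) {
  if (any(s_c_um2 < 0)) stop_units("s_c_um2 must be >= 0 (um^2)")
  if (any(d_mean_um < 0)) stop_units("d_mean_um must be >= 0 (um)")
  s_c_um2 * d_mean_um
}
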