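#' Per-frame wound-assay metrics
#'
#' Computes, for one background-corrected phase frame and a cell mask, the
#' covered area `S_c`, the mean phase over the mask, the dry mass, the
#' mean thickness, the layer volume `V = S_c * d_mean`, and (if a mean
#' single-cell dry mass is supplied) an estimated cell-equivalent count.
#' An empty mask is a valid observation: all metrics are zero.
#'
#' The fields are algebraically linked: `DM = (n_cell - n_medium) * V /
#' alpha` holds exactly because both sides reduce to the same integrated
#' phase.
#'
#' @param img a background-corrected [phase_image()].
#' @param mask logical matrix (cell-covered region), may be empty.
#' @param n_cell integral refractive index assumed for the layer
#'   (population mean from suspended-cell fits).
#' @param cfg an [optical_config()].
#' @param dm_single_pg optional mean single-cell dry mass in pg.
#' @return A one-row data frame: `time_min`, `S_c_um2`, `mean_phase_rad`,
#'   `dry_mass_pg`, `d_mean_um`, `volume_um3` and, when `dm_single_pg`
#'   is given, `n_cells_est`.
#' @export
compute_frame_metrics <- function(img, mask, n_cell, cfg,
                                  dm_single_pg = NULL) {
  stopifnot(inherits(img, "phase_image"), inherits(cfg, "optical_config"))
  check_pitch(img, cfg)
  check_mask(mask, img, require_nonempty = FALSE)
  if (!any(mask)) {
    out <- data.frame(time_min = img$time_min, S_c_um2 = 0,
                      mean_phase_rad = 0, dry_mass_pg = 0, d_mean_um = 0,
                      volume_um3 = 0)
  } else {
    s_c <- mask_area(mask, img$pixel_pitch_um)
    mphi <- mean(img$values[mask])
    dm <- dry_mass(img, mask, cfg)
    d_mean <- mean_thickness(img, mask, n_cell, cfg)
    out <- data.frame(time_min = img$time_min, S_c_um2 = s_c,
                      mean_phase_rad = mphi, dry_mass_pg = dm,
                      d_mean_um = d_mean,
                      volume_um3 = layer_volume(s_c, d_mean))
  }
  if (!is.null(dm_single_pg)) {
    out$n_cells_est <- estimate_cell_number(out$dry_mass_pg, dm_single_pg,
                                            warn = FALSE)
  }
  out
}

#' Relative time series of wound metrics
#'
#' Converts absolute per-frame metrics into the quantities tracked during
#' wound closure: area and dry mass are reported relative to the first
#' frame (`dS_c`, `dDM`), while mean thickness and volume stay absolute.
#'
#' @param frames data frame of per-frame metrics (rows time-ordered,
#'   columns as produced by [compute_frame_metrics()]).
#' @return The input with added columns `dS_c_um2` and `dDM_pg`.
#' @export
relative_series <- function(frames) {
  if (!is.data.frame(frames) || nrow(frames) < 2) {
    stop_units("need at least two time-ordered frames")
  }
  if (is.unsorted(frames$time_min, strictly = FALSE)) {
    stop_units("frames are not time-ordered")
  }
  frames$dS_c_um2 <- frames$S_c_um2 - frames$S_c_um2[1]
  frames$dDM_pg <- frames$dry_mass_pg - frames$dry_mass_pg[1]
  frames
}

#' Estimate the number of cells from accumulated dry mass
#'
#' Divides the dry-mass change in the wound by the mean dry mass of a
#' single cell of the same condition, obtained from suspended-cell fits.
#' The quotient is fractional; a negative mass change passes through with
#' a warning (net mass loss).
#'
#' @param delta_dm_pg dry-mass change in picograms (scalar or vector).
#' @param dm_single_pg mean single-cell dry mass in picograms, `> 0`.
#' @param warn warn on negative input; default TRUE.
#' @return Estimated (fractional) cell count.
#' @export
estimate_cell_number <- function(delta_dm_pg, dm_single_pg, warn = TRUE) {
  check_scalar(dm_single_pg, "dm_single_pg")
  if (dm_single_pg <= 0) {
    stop_units("dm_single_pg must be > 0 picograms")
  }
  if (warn && any(delta_dm_pg < 0)) {
    warning("negative dry-mass change: estimated cell number is negative ",
            "(net mass loss)", call. = FALSE)
  }
  delta_dm_pg / dm_single_pg
}

# metric column -> units of its per-minute slope
rate_units <- c(
  S_c_um2 = "um2/min", dS_c_um2 = "um2/min",
  dry_mass_pg = "pg/min", dDM_pg = "pg/min",
  d_mean_um = "nm/min", volume_um3 = "um3/min",
  n_cells_est = "cells/min"
)

#' Per-minute rate constants by linear regression
#'
#' Fits an ordinary-least-squares line through each selected metric versus
#' time and reports the slope with its regression standard error. When a
#' list of replicate series is given, the replicates are averaged
#' per time point first and the regression runs on the averaged series
#' (replicates must share one time grid). Thickness slopes are reported
#' in nm/min; all other slopes in their natural unit per minute.
#'
#' @param series a data frame with a `time_min` column, or a list of such
#'   data frames (replicates on a common time grid).
#' @param metrics character vector of metric columns to regress.
#' @return A data frame of class `rate_estimates` with columns `metric`,
#'   `slope`, `se`, `units`, `n_frames`, `n_replicates`.
#' @export
estimate_rates <- function(series,
                           metrics = c("S_c_um2", "dry_mass_pg",
                                       "d_mean_um", "volume_um3")) {
  if (is.data.frame(series)) series <- list(series)
  n_rep <- length(series)
  grids <- lapply(series, function(s) s$time_min)
  if (n_rep > 1) {
    for (g in grids[-1]) {
      if (length(g) != length(grids[[1]]) ||
          !isTRUE(all.equal(g, grids[[1]]))) {
        stop_units("replicate time grids mismatch: align replicates on a ",
                   "common grid before averaging")
      }
    }
  }
  t <- grids[[1]]
  if (length(t) < 3) {
    stop_units("need at least 3 time points for a rate estimate; got ",
               length(t))
  }
  metrics <- intersect(metrics, Reduce(intersect, lapply(series, names)))
  if (length(metrics) == 0) stop_units("no requested metric column present")
  rows <- lapply(metrics, function(m) {
    y <- rowMeans(do.call(cbind, lapply(series, `[[`, m)))
    fit <- stats::lm(y ~ t)
    # summary() warns on exact linear input ("essentially perfect fit");
    # a zero SE is the correct answer there
    sm <- suppressWarnings(summary(fit))$coefficients
    slope <- sm["t", "Estimate"]
    se <- sm["t", "Std. Error"]
    scale <- if (m == "d_mean_um") 1000 else 1   # um/min -> nm/min
    unit <- if (m %in% names(rate_units)) unname(rate_units[m]) else "per min"
    data.frame(metric = m, slope = slope * scale, se = se * scale,
               units = unit,
               n_frames = length(t), n_replicates = n_rep)
  })
  structure(do.call(rbind, rows), class = c("rate_estimates", "data.frame"))
}

#' Averaged thickness profile across the wound
#'
#' Converts phase to thickness pixel-wise and averages it along one axis
#' within a band, producing the 1-D thickness profile through the cell
#' layer (position in micrometres along the other axis).
#'
#' @param img a background-corrected [phase_image()].
#' @param n_cell integral refractive index, `> n_medium`.
#' @param cfg an [optical_config()].
#' @param axis `"x"`: profile along x, averaging over rows (the default);
#'   `"y"`: profile along y, averaging over columns.
#' @param band optional logical matrix restricting the average; must be
#'   non-empty.
#' @return A data frame `position_um`, `thickness_um` (positions with no
#'   band pixels are dropped).
#' @export
thickness_profile <- function(img, n_cell, cfg, axis = c("x", "y"),
                              band = NULL) {
  stopifnot(inherits(img, "phase_image"), inherits(cfg, "optical_config"))
  axis <- match.arg(axis)
  check_pitch(img, cfg)
  if (n_cell <= cfg$n_medium) {
    stop_units("degenerate contrast: n_cell must exceed n_medium")
  }
  if (is.null(band)) {
    band <- matrix(TRUE, nrow(img$values), ncol(img$values))
  }
  check_mask(band, img)
  d <- img$values * cfg$wavelength_um / (2 * pi * (n_cell - cfg$n_medium))
  d[!band] <- NA
  prof <- if (axis == "x") colMeans(d, na.rm = TRUE) else rowMeans(d, na.rm = TRUE)
  pos <- (seq_along(prof) - 1) * img$pixel_pitch_um
  keep <- !is.nan(prof)
  data.frame(position_um = pos[keep], thickness_um = prof[keep])
}
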