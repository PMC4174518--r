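# Synthetic inputs with planted, recorded ground truth. The generators
# emulate the two experimental situations the analysis addresses:
# suspended near-spherical single cells, and a two-front wound assay whose
# fronts advance and thicken linearly in time.

#' Synthetic phase image of a suspended spherical cell
#'
#' Evaluates the spherical phase model at every pixel centre, optionally
#' adding iid Gaussian phase noise. Deterministic given a seed.
#'
#' @param radius_um sphere radius in micrometres.
#' @param n_cell integral refractive index.
#' @param cfg an [optical_config()]; supplies wavelength, medium index and
#'   pixel pitch.
#' @param center_um optional `(x, y)` centre in micrometres; default the
#'   field centre.
#' @param field_um `(width, height)` of the field in micrometres; default
#'   a square of 4 radii. The sphere footprint must lie inside the field.
#' @param noise_sd Gaussian phase-noise standard deviation in radians.
#' @param seed optional integer seed for the noise.
#' @return A [phase_image()].
#' @export
make_sphere_image <- function(radius_um, n_cell, cfg, center_um = NULL,
                              field_um = NULL, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(cfg, "optical_config"))
  if (radius_um <= 0) stop_units("radius_um must be > 0")
  pitch <- cfg$pixel_pitch_um
  field_um <- field_um %||% rep(4 * radius_um, 2)
  dims <- c(round(field_um[2] / pitch), round(field_um[1] / pitch))  # rows, cols
  extent <- c((dims[2] - 1), (dims[1] - 1)) * pitch                  # x, y
  center_um <- center_um %||% (extent / 2)
  if (center_um[1] - radius_um < 0 || center_um[1] + radius_um > extent[1] ||
      center_um[2] - radius_um < 0 || center_um[2] + radius_um > extent[2]) {
    stop_units("sphere footprint (centre ", paste(round(center_um, 2),
               collapse = ", "), " um, radius ", radius_um,
               " um) is clipped by the field")
  }
  g <- pixel_grid(dims, pitch)
  v <- sphere_phase_model(g$x, g$y, center_um, radius_um, n_cell, cfg)
  if (noise_sd > 0) {
    v <- v + with_seed(seed, matrix(stats::rnorm(length(v), sd = noise_sd),
                                    dims[1], dims[2]))
  }
  phase_image(v, pitch)
}

#' Specification of a suspended-cell population
#'
#' Radius and refractive index are drawn from independent truncated
#' normals (radius `> 1` um, index `> n_medium + 0.001`). Defaults mirror
#' an untreated epithelial control population: 89 cells of radius
#' 7.2 +/- 1.2 um and index 1.3713 +/- 0.0057 (population SDs).
#'
#' @param n_cells number of cells.
#' @param radius_mean_um,radius_sd_um radius distribution in micrometres.
#' @param n_cell_mean,n_cell_sd refractive-index distribution. The default
#'   SD is the control-population SE of 0.0006 scaled by `sqrt(89)`.
#' @param noise_sd per-image Gaussian phase noise (radians).
#' @param seed integer seed.
#' @return An object of class `sphere_population_spec`.
#' @export
sphere_population_spec <- function(n_cells = 89, radius_mean_um = 7.2,
                                   radius_sd_um = 1.2,
                                   n_cell_mean = 1.3713,
                                   n_cell_sd = 0.0006 * sqrt(89),
                                   noise_sd = 0.05, seed = 1L) {
  if (n_cells < 1) stop_units("n_cells must be >= 1")
  if (radius_mean_um <= 0 || n_cell_mean <= 0) {
    stop_units("population means must be positive")
  }
  if (radius_sd_um < 0 || n_cell_sd < 0) stop_units("population SDs must be >= 0")
  structure(list(n_cells = as.integer(n_cells),
                 radius_mean_um = radius_mean_um, radius_sd_um = radius_sd_um,
                 n_cell_mean = n_cell_mean, n_cell_sd = n_cell_sd,
                 noise_sd = noise_sd, seed = seed),
            class = "sphere_population_spec")
}

rtruncnorm <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw > lower])
  }
  out[seq_len(n)]
}

#' Generate a synthetic suspended-cell population
#'
#' @param spec a [sphere_population_spec()].
#' @param cfg an [optical_config()].
#' @return A list: `images` (list of [phase_image()]) and `truth` (data
#'   frame of the planted radius, index, volume and dry mass per cell).
#' @export
make_sphere_population <- function(spec, cfg) {
  stopifnot(inherits(spec, "sphere_population_spec"),
            inherits(cfg, "optical_config"))
  if (spec$n_cell_mean <= cfg$n_medium) {
    stop_units("n_cell_mean must exceed n_medium")
  }
  draws <- with_seed(spec$seed, {
    r <- rtruncnorm(spec$n_cells, spec$radius_mean_um, spec$radius_sd_um, 1)
    n <- rtruncnorm(spec$n_cells, spec$n_cell_mean, spec$n_cell_sd,
                    cfg$n_medium + 0.001)
    list(r = r, n = n,
         img_seeds = sample.int(.Machine$integer.max, spec$n_cells))
  })
  field <- rep(4 * max(draws$r), 2)
  images <- lapply(seq_len(spec$n_cells), function(i) {
    make_sphere_image(draws$r[i], draws$n[i], cfg, field_um = field,
                      noise_sd = spec$noise_sd, seed = draws$img_seeds[i])
  })
  vol <- (4 / 3) * pi * draws$r^3
  truth <- data.frame(
    cell = seq_len(spec$n_cells),
    radius_um = draws$r,
    n_cell = draws$n,
    volume_um3 = vol,
    dry_mass_pg = (draws$n - cfg$n_medium) * vol / cfg$alpha_um3_per_pg
  )
  list(images = images, truth = truth)
}

#' Specification of a synthetic wound assay
#'
#' Two confluent plateaus separated by a cell-free gap; each front
#' advances into the gap at a constant speed (negative = retreat) while
#' its plateau thickness changes at a constant rate, matching the
#' near-linear kinetics observed in insert-based wound assays. Defaults:
#' a 500-um gap imaged every 30 min for 40 h (81 frames).
#'
#' @param field_um `(width, height)` in micrometres.
#' @param gap_start_um,gap_end_um initial gap limits along x.
#' @param front_speed front speeds in um/min, named `left`/`right`.
#' @param thickness0_um initial plateau thicknesses (um), `left`/`right`.
#' @param thickness_rate_nm_per_min thickness change rates (nm/min).
#' @param n_cell per-side integral refractive indices.
#' @param frame_interval_min time between frames; default 30.
#' @param n_frames number of frames; default 81.
#' @param noise_sd Gaussian phase noise SD (radians).
#' @param edge_amplitude_um,edge_period_um sinusoidal front roughness.
#' @param seed integer seed.
#' @return An object of class `assay_spec`.
#' @export
assay_spec <- function(field_um = c(700, 110),
                       gap_start_um = 100, gap_end_um = 600,
                       front_speed = c(left = 0.21, right = 0),
                       thickness0_um = c(left = 5, right = 5),
                       thickness_rate_nm_per_min = c(left = 0.51, right = 0.51),
                       n_cell = c(left = 1.3713, right = 1.3713),
                       frame_interval_min = 30, n_frames = 81,
                       noise_sd = 0, edge_amplitude_um = 0,
                       edge_period_um = 50, seed = 1L) {
  if (frame_interval_min <= 0) stop_units("frame_interval_min must be > 0")
  if (n_frames < 2) stop_units("n_frames must be >= 2")
  if (gap_end_um <= gap_start_um) stop_units("gap_end_um must exceed gap_start_um")
  t_end <- (n_frames - 1) * frame_interval_min
  fl <- gap_start_um + front_speed[["left"]] * t_end + edge_amplitude_um
  fr <- gap_end_um - front_speed[["right"]] * t_end - edge_amplitude_um
  if (fl >= fr) {
    stop_units("fronts collide mid-gap before the last frame: ",
               "shorten the series or slow the fronts")
  }
  lims_l <- gap_start_um + front_speed[["left"]] * c(0, t_end)
  lims_r <- gap_end_um - front_speed[["right"]] * c(0, t_end)
  if (min(lims_l) < 0 || max(lims_r) > field_um[1]) {
    stop_units("a front leaves the field during the series")
  }
  if (any(thickness0_um < 0)) stop_units("thicknesses must be >= 0")
  structure(list(field_um = field_um, gap_start_um = gap_start_um,
                 gap_end_um = gap_end_um, front_speed = front_speed,
                 thickness0_um = thickness0_um,
                 thickness_rate_nm_per_min = thickness_rate_nm_per_min,
                 n_cell = n_cell, frame_interval_min = frame_interval_min,
                 n_frames = as.integer(n_frames), noise_sd = noise_sd,
                 edge_amplitude_um = edge_amplitude_um,
                 edge_period_um = edge_period_um, seed = seed),
            class = "assay_spec")
}

#' Generate a synthetic wound-assay time-lapse with ground truth
#'
#' Rasterizes the two-plateau front model per frame (pixel centres decide
#' coverage) and computes the planted ground truth in closed form,
#' restricted to the initial gap region: per-frame covered area, mean
#' thickness, layer volume and dry mass, internally consistent with the
#' phase/thickness/mass relations.
#'
#' @param spec an [assay_spec()].
#' @param cfg an [optical_config()].
#' @return A list of class `wound_assay`: `stack` (list of
#'   [phase_image()]), `truth` (per-frame data frame), `geometry`
#'   (a [wound_geometry()] of the initial gap) and `spec`.
#' @export
make_wound_assay <- function(spec, cfg) {
  stopifnot(inherits(spec, "assay_spec"), inherits(cfg, "optical_config"))
  pitch <- cfg$pixel_pitch_um
  dims <- c(round(spec$field_um[2] / pitch), round(spec$field_um[1] / pitch))
  g <- pixel_grid(dims, pitch)
  x_row <- g$x[1, ]                       # x per column
  y_col <- g$y[, 1]                       # y per row
  times <- (seq_len(spec$n_frames) - 1) * spec$frame_interval_min
  rough <- if (spec$edge_amplitude_um > 0) {
    spec$edge_amplitude_um * sin(2 * pi * y_col / spec$edge_period_um)
  } else {
    rep(0, dims[1])
  }
  noise_seeds <- if (spec$noise_sd > 0) {
    with_seed(spec$seed, sample.int(.Machine$integer.max, spec$n_frames))
  } else {
    rep(NA_integer_, spec$n_frames)
  }
  gap_w <- spec$gap_end_um - spec$gap_start_um
  height_um <- dims[1] * pitch
  stack <- vector("list", spec$n_frames)
  truth <- vector("list", spec$n_frames)
  for (k in seq_len(spec$n_frames)) {
    t <- times[k]
    front_l <- spec$gap_start_um + spec$front_speed[["left"]] * t + rough
    front_r <- spec$gap_end_um - spec$front_speed[["right"]] * t - rough
    d_l <- spec$thickness0_um[["left"]] +
      spec$thickness_rate_nm_per_min[["left"]] / 1000 * t
    d_r <- spec$thickness0_um[["right"]] +
      spec$thickness_rate_nm_per_min[["right"]] / 1000 * t
    phi_l <- phase_from_thickness(max(d_l, 0), spec$n_cell[["left"]], cfg)
    phi_r <- phase_from_thickness(max(d_r, 0), spec$n_cell[["right"]], cfg)
    left_cov <- outer(front_l, x_row, function(f, x) x <= f)
    right_cov <- outer(front_r, x_row, function(f, x) x >= f)
    v <- phi_l * left_cov + phi_r * right_cov
    if (spec$noise_sd > 0) {
      v <- v + with_seed(noise_seeds[k],
                         matrix(stats::rnorm(length(v), sd = spec$noise_sd),
                                dims[1], dims[2]))
    }
    stack[[k]] <- phase_image(v, pitch, time_min = t)
    # closed-form truth within the initial gap, averaged over the front
    # roughness profile (exact for the rasterization-free continuum)
    in_l <- mean(pmin(pmax(front_l - spec$gap_start_um, 0), gap_w))
    in_r <- mean(pmin(pmax(spec$gap_end_um - front_r, 0), gap_w))
    area_l <- in_l * height_um
    area_r <- in_r * height_um
    vol <- area_l * d_l + area_r * d_r
    dm <- (spec$n_cell[["left"]] - cfg$n_medium) * area_l * d_l /
      cfg$alpha_um3_per_pg +
      (spec$n_cell[["right"]] - cfg$n_medium) * area_r * d_r /
      cfg$alpha_um3_per_pg
    area <- area_l + area_r
    truth[[k]] <- data.frame(
      time_min = t, area_um2 = area,
      d_mean_um = if (area > 0) vol / area else 0,
      volume_um3 = vol, dry_mass_pg = dm)
  }
  structure(
    list(stack = stack, truth = do.call(rbind, truth),
         geometry = wound_geometry("x", spec$gap_start_um, spec$gap_end_um),
         spec = spec),
    class = "wound_assay"
  )
}

#' Encode a phase stack as off-axis holograms
#'
#' Applies [simulate_hologram()] frame-wise, enabling end-to-end tests
#' that start from raw interference images.
#'
#' @param stack list of [phase_image()] frames.
#' @param carrier `(fx, fy)` in cycles/pixel.
#' @param object_amp,ref_amp wave amplitudes.
#' @param noise_sd intensity noise SD.
#' @param seed integer seed; per-frame seeds are derived from it.
#' @return List of `hologram` objects.
#' @export
encode_assay_holograms <- function(stack, carrier, object_amp = 1,
                                   ref_amp = 1, noise_sd = 0, seed = NULL) {
  frame_seeds <- if (!is.null(seed)) {
    with_seed(seed, sample.int(.Machine$integer.max, length(stack)))
  } else {
    rep(list(NULL), length(stack))
  }
  lapply(seq_along(stack), function(k) {
    simulate_hologram(stack[[k]], carrier, object_amp, ref_amp, noise_sd,
                      seed = if (is.null(seed)) NULL else frame_seeds[[k]])
  })
}
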