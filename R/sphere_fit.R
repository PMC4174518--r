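#' Phase of a spherical cell
#'
#' A suspended near-spherical cell of radius `r` and integral refractive
#' index `n_cell` has thickness `d(rho) = 2*sqrt(r^2 - rho^2)` along the
#' optical axis at distance `rho` from its centre, so its phase footprint
#' is `Delta_phi(rho) = (4*pi/lambda)*(n_cell - n_medium)*sqrt(r^2 - rho^2)`
#' inside the footprint and 0 outside, peaking at
#' `(4*pi/lambda)*Delta_n*r` in the centre.
#'
#' @param x,y coordinates in micrometres (vectors or matrices of equal
#'   shape).
#' @param center numeric `(x, y)` centre in micrometres.
#' @param radius sphere radius in micrometres, `> 0`.
#' @param n_cell integral refractive index.
#' @param cfg an [optical_config()].
#' @return Phase in radians, same shape as `x`.
#' @export
sphere_phase_model <- function(x, y, center, radius, n_cell, cfg) {
  stopifnot(inherits(cfg, "optical_config"))
  if (radius <= 0) stop_units("radius must be > 0 (micrometres)")
  rho2 <- (x - center[1])^2 + (y - center[2])^2
  d <- 2 * sqrt(pmax(radius^2 - rho2, 0))
  (2 * pi / cfg$wavelength_um) * (n_cell - cfg$n_medium) * d
}

#' Fit the spherical-cell model to a phase image
#'
#' Recovers centre, radius and integral refractive index of one suspended
#' near-spherical cell by nonlinear least squares on the spherical phase
#' model, then derives volume (`4/3*pi*r^3`) and dry mass
#' (`Delta_n * V / alpha`). Initialisation is deterministic: the centre
#' from the phase-weighted centroid of the thresholded blob, the radius
#' from its equivalent-area circle, and the index from the peak phase via
#' the closed form. The fit window is the blob bounding box dilated by
#' 25%; pixels outside the model footprint contribute with model value 0,
#' anchoring the background.
#'
#' @param img a [phase_image()] containing one dominant compact blob of
#'   positive phase.
#' @param cfg an [optical_config()].
#' @param init optional named list overriding initial values
#'   (`center`, `radius`, `n_cell`).
#' @param blob_threshold phase level (radians) above which pixels count as
#'   blob; default 0.5. An image with no pixel above it is an error.
#' @param window_dilate fractional dilation of the fitting window.
#' @return An object of class `sphere_fit_result`: a list with `center_um`,
#'   `radius_um`, `n_cell`, `volume_um3`, `dry_mass_pg`, `rmse_rad`,
#'   `n_pixels_fit`.
#' @export
fit_sphere <- function(img, cfg, init = NULL, blob_threshold = 0.5,
                       window_dilate = 0.25) {
  stopifnot(inherits(img, "phase_image"), inherits(cfg, "optical_config"))
  check_pitch(img, cfg)
  v <- img$values
  pitch <- img$pixel_pitch_um
  blob <- v > blob_threshold
  if (!any(blob)) {
    stop_units("no blob found: maximum phase ", sprintf("%.3g", max(v)),
               " rad is below the threshold of ", blob_threshold, " rad")
  }
  idx <- which(blob, arr.ind = TRUE)
  wts <- v[blob]
  # 0-based pixel-centre coordinates in um
  cx0 <- sum((idx[, 2] - 1) * wts) / sum(wts) * pitch
  cy0 <- sum((idx[, 1] - 1) * wts) / sum(wts) * pitch
  r0 <- sqrt(sum(blob) * pitch^2 / pi)
  n0 <- cfg$n_medium + max(v) * cfg$wavelength_um / (4 * pi * r0)
  if (!is.null(init)) {
    cx0 <- init$center[1] %||% cx0
    cy0 <- init$center[2] %||% cy0
    r0 <- init$radius %||% r0
    n0 <- init$n_cell %||% n0
  }
  # fitting window: blob bounding box dilated by window_dilate
  rr <- range(idx[, 1]); cc <- range(idx[, 2])
  dil_r <- ceiling(diff(rr) * window_dilate / 2) + 1
  dil_c <- ceiling(diff(cc) * window_dilate / 2) + 1
  rows <- max(1, rr[1] - dil_r):min(nrow(v), rr[2] + dil_r)
  cols <- max(1, cc[1] - dil_c):min(ncol(v), cc[2] + dil_c)
  xw <- outer(rep(1, length(rows)), (cols - 1) * pitch)
  yw <- outer((rows - 1) * pitch, rep(1, length(cols)))
  data <- v[rows, cols]
  resid_fn <- function(p) {
    as.vector(sphere_phase_model(xw, yw, c(p[1], p[2]), p[3], p[4], cfg) - data)
  }
  fit <- minpack.lm::nls.lm(
    par = c(cx0, cy0, r0, n0),
    fn = resid_fn,
    lower = c(-Inf, -Inf, pitch, cfg$n_medium + 1e-6),
    upper = c(Inf, Inf, Inf, 1.5),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (!(fit$info %in% 1:4)) {
    stop_units("sphere fit did not converge (info = ", fit$info, ", ",
               fit$message, "); residual sum of squares ",
               sprintf("%.4g", fit$deviance))
  }
  p <- fit$par
  radius <- p[3]
  n_cell <- p[4]
  volume <- (4 / 3) * pi * radius^3
  structure(
    list(
      center_um = c(x = p[1], y = p[2]),
      radius_um = radius,
      n_cell = n_cell,
      volume_um3 = volume,
      dry_mass_pg = sphere_dry_mass(volume, n_cell, cfg),
      rmse_rad = sqrt(mean(fit$fvec^2)),
      n_pixels_fit = length(fit$fvec)
    ),
    class = "sphere_fit_result"
  )
}

#' @export
print.sphere_fit_result <- function(x, ...) {
  cat(sprintf("Sphere fit: r = %.3f um, n_cell = %.5f, V = %.1f um^3, DM = %.1f pg (rmse %.4g rad, %d px)\n",
              x$radius_um, x$n_cell, x$volume_um3, x$dry_mass_pg,
              x$rmse_rad, x$n_pixels_fit))
  invisible(x)
}

#' Fit a population of suspended cells
#'
#' Applies [fit_sphere()] to every image in a stack and summarises the
#' population: per-cell results and mean with standard error
#' (`SE = SD/sqrt(n)`) for radius, refractive index, volume and dry mass.
#' Failed fits are recorded and excluded from the summary.
#'
#' @param imgs list of [phase_image()] objects, one cell per image.
#' @param cfg an [optical_config()].
#' @param ... passed to [fit_sphere()].
#' @return A list of class `sphere_population`: `cells` (data frame, one
#'   row per successful fit), `summary` (data frame of mean/SE/n per
#'   parameter), `n_failed`, `failures` (messages).
#' @export
batch_fit <- function(imgs, cfg, ...) {
  if (length(imgs) < 1) stop_units("need at least one image")
  rows <- list()
  failures <- character()
  for (i in seq_along(imgs)) {
    res <- tryCatch(fit_sphere(imgs[[i]], cfg, ...), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("cell %d: %s", i, conditionMessage(res)))
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      cell = i,
      center_x_um = res$center_um[["x"]],
      center_y_um = res$center_um[["y"]],
      radius_um = res$radius_um,
      n_cell = res$n_cell,
      volume_um3 = res$volume_um3,
      dry_mass_pg = res$dry_mass_pg,
      rmse_rad = res$rmse_rad
    )
  }
  if (length(rows) == 0) {
    stop_units("all ", length(imgs), " sphere fits failed; first failure: ",
               failures[1])
  }
  cells <- do.call(rbind, rows)
  if (length(failures) > 0) {
    message(length(failures), " of ", length(imgs), " sphere fits failed ",
            "and were excluded from the population summary")
  }
  params <- c("radius_um", "n_cell", "volume_um3", "dry_mass_pg")
  n <- nrow(cells)
  summary <- data.frame(
    parameter = params,
    mean = vapply(params, function(p) mean(cells[[p]]), numeric(1)),
    se = vapply(params, function(p) {
      if (n < 2) NA_real_ else stats::sd(cells[[p]]) / sqrt(n)
    }, numeric(1)),
    n_cells = n,
    row.names = NULL
  )
  structure(
    list(cells = cells, summary = summary,
         n_failed = length(failures), failures = failures),
    class = "sphere_population"
  )
}

#' @export
print.sphere_population <- function(x, ...) {
  cat(sprintf("Sphere population: %d cells fitted, %d failed\n",
              nrow(x$cells), x$n_failed))
  print(x$summary, digits = 5)
  invisible(x)
}

#' Write per-cell sphere-fit results and a JSON summary
#'
#' @param pop a `sphere_population` from [batch_fit()].
#' @param csv_path path for the per-cell CSV table.
#' @param json_path optional path for a JSON population summary.
#' @return Invisibly, the paths written.
#' @export
write_population <- function(pop, csv_path, json_path = NULL) {
  stopifnot(inherits(pop, "sphere_population"))
  utils::write.csv(pop$cells, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(summary = pop$summary, n_failed = pop$n_failed),
      json_path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(c(csv_path, json_path))
}
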