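#' Wound-gap geometry
#'
#' Describes the initial cell-free region of a wound assay, fixed across
#' the time series: either an axis-aligned band (the usual culture-insert
#' gap) or a polygon in micrometre coordinates.
#'
#' @param axis `"x"` (gap bounded by vertical fronts, the default) or
#'   `"y"`; ignored for polygons.
#' @param gap_start_um,gap_end_um band limits in micrometres along `axis`.
#' @param polygon optional two-column matrix of `(x, y)` vertices in
#'   micrometres; overrides the band.
#' @return An object of class `wound_geometry`.
#' @export
wound_geometry <- function(axis = c("x", "y"), gap_start_um = NULL,
                           gap_end_um = NULL, polygon = NULL) {
  axis <- match.arg(axis)
  if (is.null(polygon)) {
    check_scalar(gap_start_um, "gap_start_um")
    check_scalar(gap_end_um, "gap_end_um")
    if (gap_end_um <= gap_start_um) {
      stop_units("degenerate gap: gap_end_um must exceed gap_start_um")
    }
  } else {
    polygon <- as.matrix(polygon)
    if (ncol(polygon) != 2 || nrow(polygon) < 3) {
      stop_units("polygon must be an n x 2 matrix of (x, y) um with n >= 3")
    }
  }
  structure(list(axis = axis, gap_start_um = gap_start_um,
                 gap_end_um = gap_end_um, polygon = polygon),
            class = "wound_geometry")
}

# Rasterize a wound geometry to a logical mask for an image of dimensions
# `dim` (rows, cols) at pixel pitch `pitch`. Pixel centres are 0-based
# indices times the pitch.
geometry_mask <- function(geom, dim, pitch) {
  stopifnot(inherits(geom, "wound_geometry"))
  g <- pixel_grid(dim, pitch)
  if (is.null(geom$polygon)) {
    coord <- if (geom$axis == "x") g$x else g$y
    coord >= geom$gap_start_um & coord <= geom$gap_end_um
  } else {
    matrix(point_in_polygon(as.vector(g$x), as.vector(g$y), geom$polygon),
           dim[1], dim[2])
  }
}

# Even-odd ray-casting point-in-polygon test, vectorized over points.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Otsu threshold of non-negative phase values (radians). Values below zero
# are clipped to zero before building the histogram.
otsu_threshold <- function(values, levels = 256) {
  v <- pmax(values, 0)
  top <- max(v)
  if (top <= 0) return(Inf)
  EBImage::otsu(v / top, range = c(0, 1), levels = levels) * top
}

#' Segment the cell-covered area of a phase image
#'
#' Pixels with phase above a threshold after optional Gaussian smoothing
#' form the cell mask; morphological closing, removal of small objects and
#' filling of small holes clean it up. The threshold `"auto"` uses Otsu's
#' method on the phase histogram clipped at zero, floored at three times
#' the robust (median-absolute-deviation) background noise level so an
#' empty, noisy frame yields an empty mask.
#'
#' @param img a background-corrected [phase_image()] (cell-free level
#'   near 0).
#' @param threshold phase threshold in radians, or `"auto"`.
#' @param smooth_sigma_px Gaussian pre-smoothing sigma in pixels; 0
#'   disables smoothing. Default 1.
#' @param close_disc_px diameter of the disc used for morphological
#'   closing; 0 disables. Default 3.
#' @param min_object_um2 connected components smaller than this are
#'   removed. Default 50.
#' @param min_hole_um2 interior holes smaller than this are filled.
#'   Default 50.
#' @return A logical matrix (the cell mask); its area is
#'   `mask_area(mask, pitch)`.
#' @export
segment_cells <- function(img, threshold = "auto", smooth_sigma_px = 1,
                          close_disc_px = 3, min_object_um2 = 50,
                          min_hole_um2 = 50) {
  stopifnot(inherits(img, "phase_image"))
  v <- img$values
  pitch <- img$pixel_pitch_um
  if (smooth_sigma_px > 0) {
    v <- EBImage::gblur(v, sigma = smooth_sigma_px, boundary = "replicate")
  }
  if (identical(threshold, "auto")) {
    th <- otsu_threshold(v)
    if (is.finite(th)) {
      bg <- v[v < th]
      noise_sd <- if (length(bg) > 1) stats::mad(bg, center = 0) else 0
      th <- max(th, 3 * noise_sd)
    }
  } else {
    check_scalar(threshold, "threshold")
    th <- threshold
  }
  mask <- v > th
  if (!any(mask)) return(mask)
  if (close_disc_px > 0) {
    brush <- EBImage::makeBrush(close_disc_px, shape = "disc")
    mask <- EBImage::closing(mask, brush) > 0
  }
  if (min_object_um2 > 0) {
    lab <- EBImage::bwlabel(mask)
    areas <- tabulate(lab[lab > 0])
    drop <- which(areas * pitch^2 < min_object_um2)
    if (length(drop) > 0) mask[lab %in% drop] <- FALSE
  }
  if (min_hole_um2 > 0 && any(mask)) {
    holes <- EBImage::bwlabel(!mask)
    border_labels <- unique(c(holes[1, ], holes[nrow(holes), ],
                              holes[, 1], holes[, ncol(holes)]))
    areas <- tabulate(holes[holes > 0])
    fill <- setdiff(which(areas * pitch^2 < min_hole_um2), border_labels)
    if (length(fill) > 0) mask[holes %in% fill] <- TRUE
  }
  mask
}

#' Cell-covered area inside the wound gap over time
#'
#' Segments each frame, restricts the mask to the (fixed) wound geometry,
#' and reports the covered area `S_c` within the gap per frame together
#' with its change relative to the first frame. Pure bookkeeping: no
#' smoothing is applied to the series, and `dS_c(t0) = 0` by construction.
#'
#' @param stack list of [phase_image()] frames, time-ordered; all frames
#'   must share one shape.
#' @param geometry a [wound_geometry()].
#' @param threshold passed to [segment_cells()].
#' @param ... further arguments passed to [segment_cells()].
#' @return A data frame with columns `time_min`, `S_c_um2`, `dS_c_um2`.
#' @export
gap_coverage_series <- function(stack, geometry, threshold = "auto", ...) {
  if (length(stack) < 1) stop_units("empty stack")
  dims <- lapply(stack, function(f) dim(f$values))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop_units("frames have differing shapes")
  }
  pitch <- stack[[1]]$pixel_pitch_um
  gap <- geometry_mask(geometry, dims[[1]], pitch)
  times <- vapply(stack, function(f) f$time_min, numeric(1))
  if (any(is.na(times))) times <- seq_along(stack) - 1
  if (is.unsorted(times, strictly = FALSE)) {
    stop_units("frames are not time-ordered")
  }
  s_c <- vapply(stack, function(f) {
    mask <- segment_cells(f, threshold = threshold, ...)
    mask_area(mask & gap, pitch)
  }, numeric(1))
  data.frame(time_min = times, S_c_um2 = s_c, dS_c_um2 = s_c - s_c[1])
}

#' Label connected cell regions
#'
#' Best-effort single-cell identification by connected-component
#' labelling; touching cells merge into one label (no watershed splitting
#' is attempted).
#'
#' @param mask logical matrix from [segment_cells()].
#' @param pixel_pitch_um pixel pitch in micrometres.
#' @param min_area_um2 components smaller than this are discarded.
#' @return A list with `labels` (integer matrix, 0 = background),
#'   `n` (number of retained regions) and `areas_um2`.
#' @export
label_cells <- function(mask, pixel_pitch_um, min_area_um2 = 50) {
  if (!is.logical(mask) || !is.matrix(mask)) {
    stop_units("mask must be a logical matrix")
  }
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) {
    return(list(labels = lab, n = 0L, areas_um2 = numeric(0)))
  }
  areas <- tabulate(lab[lab > 0]) * pixel_pitch_um^2
  keep <- which(areas >= min_area_um2)
  relab <- integer(max(lab) + 1)          # old label -> new label, +1 offset
  relab[keep + 1] <- seq_along(keep)
  labels <- matrix(relab[lab + 1], nrow(lab), ncol(lab))
  list(labels = labels, n = length(keep), areas_um2 = areas[keep])
}
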