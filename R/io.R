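# TIFF stack I/O. Phase maps are stored as 32-bit TIFF pages normalized
# to [0, 1] by a power-of-two affine transform whose offset and scale
# live in a JSON sidecar next to the file (together with frame times and
# pixel pitch). Storage quantizes the normalized range to 32 bits, so a
# round trip is accurate to scale * 2^-32 (typically below 1e-8 rad).
# Holograms are stored as 8- or 16-bit integer TIFF pages (camera
# emulation) with the quantization gain in the sidecar.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a stack of phase images to TIFF
#'
#' @param stack a [phase_image()] or list of them (equal shapes).
#' @param path output TIFF path; a JSON sidecar `<path>.json` with the
#'   normalization, frame times and pixel pitch is written alongside.
#' @return Invisibly, `path`. The round trip through
#'   [read_phase_stack()] is accurate to the 32-bit quantization of the
#'   normalized range (below 1e-8 rad for typical phase maps).
#' @export
write_phase_stack <- function(stack, path) {
  if (inherits(stack, "phase_image")) stack <- list(stack)
  stopifnot(length(stack) >= 1, all(vapply(stack, inherits, logical(1),
                                           "phase_image")))
  vals <- lapply(stack, `[[`, "values")
  lo <- min(vapply(vals, min, numeric(1)))
  hi <- max(vapply(vals, max, numeric(1)))
  offset <- floor(lo)
  rng <- hi - offset
  scale <- if (rng <= 0) 1 else 2^ceiling(log2(rng))
  norm <- lapply(vals, function(v) (v - offset) / scale)
  tiff::writeTIFF(norm, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(format = "phase_stack", offset = offset, scale = scale,
         pixel_pitch_um = stack[[1]]$pixel_pitch_um,
         times_min = vapply(stack, `[[`, numeric(1), "time_min")),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a stack of phase images from TIFF
#'
#' Float pages are interpreted as radians. If the sidecar written by
#' [write_phase_stack()] is present it supplies the normalization, frame
#' times and pixel pitch; otherwise pixel pitch must be given and frame
#' times come from a uniform `interval_min`.
#'
#' @param path TIFF path.
#' @param interval_min uniform frame interval in minutes (used when the
#'   sidecar carries no times); required in that case for multi-frame
#'   stacks.
#' @param pixel_pitch_um pixel pitch; required without a sidecar.
#' @return A list of [phase_image()] frames, time-ordered.
#' @export
read_phase_stack <- function(path, interval_min = NULL,
                             pixel_pitch_um = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) paste(dim(p)[1:2], collapse = "x"),
                 character(1))
  if (length(unique(dims)) != 1) {
    stop_units("TIFF pages have mixed shapes: ",
               paste(unique(dims), collapse = ", "))
  }
  meta <- if (file.exists(sidecar_path(path))) {
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  } else {
    NULL
  }
  offset <- meta$offset %||% 0
  scale <- meta$scale %||% 1
  pitch <- meta$pixel_pitch_um %||% pixel_pitch_um
  if (is.null(pitch)) {
    stop_units("pixel_pitch_um is required when no sidecar is present")
  }
  times <- meta$times_min
  if (is.null(times) || all(is.na(times))) {
    if (is.null(interval_min)) {
      if (length(pages) > 1) {
        stop_units("no frame times in sidecar and no interval_min given")
      }
      times <- 0
    } else {
      times <- (seq_along(pages) - 1) * interval_min
    }
  }
  frames <- lapply(seq_along(pages), function(k) {
    v <- pages[[k]]
    if (length(dim(v)) == 3) v <- v[, , 1]    # tolerate grayscale-as-RGB
    phase_image(v * scale + offset, pitch, time_min = times[k])
  })
  ord <- order(vapply(frames, `[[`, numeric(1), "time_min"))
  frames[ord]
}

#' Write a stack of holograms to integer TIFF
#'
#' Intensities are scaled by the stack maximum (the gain) and quantized
#' to `bits` bits per sample, emulating a camera sensor; gain, carrier and
#' pixel pitch are stored in the JSON sidecar.
#'
#' @param holos a `hologram` or list of them.
#' @param path output TIFF path.
#' @param bits 8 or 16 bits per sample.
#' @return Invisibly, `path`.
#' @export
write_hologram_stack <- function(holos, path, bits = 16L) {
  if (inherits(holos, "hologram")) holos <- list(holos)
  stopifnot(length(holos) >= 1, bits %in% c(8L, 16L))
  gain <- max(vapply(holos, function(h) max(h$intensity), numeric(1)))
  if (gain <= 0) gain <- 1
  norm <- lapply(holos, function(h) pmin(pmax(h$intensity / gain, 0), 1))
  tiff::writeTIFF(norm, path, bits.per.sample = as.integer(bits))
  jsonlite::write_json(
    list(format = "hologram_stack", gain = gain,
         carrier = holos[[1]]$carrier,
         pixel_pitch_um = holos[[1]]$pixel_pitch_um, bits = bits),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a stack of holograms written by [write_hologram_stack()]
#'
#' @param path TIFF path (sidecar required).
#' @return A list of `hologram` objects.
#' @export
read_hologram_stack <- function(path) {
  if (!file.exists(sidecar_path(path))) {
    stop_units("hologram sidecar ", sidecar_path(path), " not found")
  }
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    structure(list(intensity = p * meta$gain,
                   carrier = as.numeric(meta$carrier),
                   pixel_pitch_um = meta$pixel_pitch_um),
              class = "hologram")
  })
}

#' Write a mask as an 8-bit TIFF (0/255)
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(mask * 1, path, bits.per.sample = 8L)
  invisible(path)
}
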