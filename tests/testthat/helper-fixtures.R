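# Shared fixtures: optical configurations and small image builders used
# across the suite. Everything is generated in code; no binary fixtures.

cfg_default <- function() optical_config()                       # pitch 0.5
cfg_fine <- function() optical_config(pixel_pitch_um = 0.25)

uniform_image <- function(value, n = 20, pitch = 0.5, time = NA) {
  phase_image(matrix(value, n, n), pitch, time_min = time)
}

full_mask <- function(img) matrix(TRUE, nrow(img$values), ncol(img$values))

# A smooth test field: Gaussian bump of given amplitude (rad) and width
# (um) centred in a square field of the given physical size.
gaussian_field <- function(amp = 2, sigma_um = 8, field_um = 48,
                           pitch = 0.5) {
  n <- round(field_um / pitch)
  xs <- (0:(n - 1)) * pitch
  c0 <- mean(range(xs))
  r2 <- outer((xs - c0)^2, (xs - c0)^2, "+")
  phase_image(amp * exp(-r2 / (2 * sigma_um^2)), pitch)
}

# Interior region excluding a border (default 8 px), as row/col indices.
interior <- function(values, border = 8) {
  list(rows = (border + 1):(nrow(values) - border),
       cols = (border + 1):(ncol(values) - border))
}

rmse_interior <- function(a, b, border = 8) {
  i <- interior(a, border)
  sqrt(mean((a - b)[i$rows, i$cols]^2))
}
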