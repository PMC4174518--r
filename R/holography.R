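#' Simulate an off-axis hologram from a phase image
#'
#' Models the interference of a plane reference wave, tilted to carry the
#' spatial frequency `carrier`, with an object wave delayed by the given
#' phase map:
#' `I = |O|^2 + |R|^2 + 2|O||R| cos(2*pi*(fx*x + fy*y) + Delta_phi)`,
#' with `x`, `y` 0-based pixel indices, plus optional additive Gaussian
#' intensity noise.
#'
#' @param phase a [phase_image()] giving the object-wave phase delay.
#' @param carrier numeric length-2 `(fx, fy)` carrier frequency in
#'   cycles/pixel; the magnitude must be positive and each component
#'   strictly below the Nyquist limit of 0.5.
#' @param object_amp object-wave amplitude; scalar or matrix matching the
#'   phase image.
#' @param ref_amp reference-wave amplitude (scalar, `>= 0`); `0` yields a
#'   fringe-free `|O|^2` image.
#' @param noise_sd standard deviation of additive Gaussian intensity noise.
#' @param seed optional integer making the noise reproducible.
#' @return An object of class `hologram` with fields `intensity`,
#'   `carrier`, `pixel_pitch_um`.
#' @export
simulate_hologram <- function(phase, carrier, object_amp = 1, ref_amp = 1,
                              noise_sd = 0, seed = NULL) {
  stopifnot(inherits(phase, "phase_image"))
  check_carrier(carrier)
  if (any(object_amp < 0) || ref_amp < 0) {
    stop_units("wave amplitudes must be >= 0")
  }
  dm <- dim(phase$values)
  x <- outer(rep(1, dm[1]), 0:(dm[2] - 1))
  y <- outer(0:(dm[1] - 1), rep(1, dm[2]))
  o <- object_amp
  intensity <- o^2 + ref_amp^2 +
    2 * o * ref_amp * cos(2 * pi * (carrier[1] * x + carrier[2] * y) +
                            phase$values)
  if (noise_sd > 0) {
    intensity <- intensity +
      with_seed(seed, matrix(stats::rnorm(length(intensity), sd = noise_sd),
                             dm[1], dm[2]))
  }
  structure(
    list(intensity = intensity, carrier = as.numeric(carrier),
         pixel_pitch_um = phase$pixel_pitch_um),
    class = "hologram"
  )
}

#' @export
print.hologram <- function(x, ...) {
  cat(sprintf("Off-axis hologram %d x %d px, carrier (%.4g, %.4g) cyc/px, pitch %g um\n",
              nrow(x$intensity), ncol(x$intensity), x$carrier[1], x$carrier[2],
              x$pixel_pitch_um))
  invisible(x)
}

check_carrier <- function(carrier) {
  if (!is.numeric(carrier) || length(carrier) != 2L || any(!is.finite(carrier))) {
    stop_units("carrier must be numeric (fx, fy) in cycles/pixel")
  }
  if (max(abs(carrier)) >= 0.5) {
    stop_units("carrier component at or beyond Nyquist (0.5 cycles/pixel): ",
               "sidebands would alias")
  }
  if (sqrt(sum(carrier^2)) <= 0) {
    stop_units("carrier magnitude must be positive (off-axis geometry)")
  }
  invisible(TRUE)
}

# Locate the off-origin spectral peak of a hologram and return its
# frequency in cycles/pixel, refined to sub-bin accuracy by parabolic
# interpolation of the log-modulus. Errors if no peak stands out.
detect_carrier <- function(intensity, min_prominence = 5) {
  dm <- dim(intensity)
  F <- stats::fft(intensity - mean(intensity))
  mod <- Mod(F)
  fy <- fft_freq(dm[1])
  fx <- fft_freq(dm[2])
  rr <- sqrt(outer(fy^2, fx^2, "+"))
  cand <- mod
  cand[rr < 0.02] <- 0                       # exclude the residual DC lobe
  cand[, fx < 0] <- 0                        # one half-plane: +fx sideband
  idx <- which(cand == max(cand), arr.ind = TRUE)[1, ]
  peak <- cand[idx[1], idx[2]]
  floor_level <- stats::median(mod[rr >= 0.02])
  if (peak < min_prominence * max(floor_level, .Machine$double.eps)) {
    stop_units("no detectable off-axis carrier: strongest off-origin ",
               "spectral peak is below the prominence threshold")
  }
  refine <- function(m, i, n) {
    # parabolic sub-bin refinement on log-modulus along one axis
    im <- if (i == 1) n else i - 1
    ip <- if (i == n) 1 else i + 1
    lm <- log(pmax(m[c(im, i, ip)], .Machine$double.xmin))
    den <- lm[1] - 2 * lm[2] + lm[3]
    d <- if (abs(den) > 0) 0.5 * (lm[1] - lm[3]) / den else 0
    max(-0.5, min(0.5, d))
  }
  dy <- refine(mod[, idx[2]], idx[1], dm[1])
  dx <- refine(mod[idx[1], ], idx[2], dm[2])
  c(fx[idx[2]] + dx / dm[2], fy[idx[1]] + dy / dm[1])
}

#' Reconstruct wrapped phase from an off-axis hologram
#'
#' Demodulates the carrier sideband: the hologram is multiplied by
#' `exp(-2*pi*i*(fx*x + fy*y))`, which shifts the cross term carrying the
#' object phase to zero frequency; a flat-core raised-cosine spectral
#' window then isolates it from the autocorrelation terms, and the
#' argument of the inverse transform is the wrapped object phase. This is
#' the Fourier-domain equivalent of carrier-fringe (spatial phase
#' shifting) reconstruction.
#'
#' @param holo a `hologram`.
#' @param carrier_hint optional `(fx, fy)` overriding the hologram's
#'   stored carrier; if both are absent the carrier is detected from the
#'   spectrum (error if no off-origin peak stands out).
#' @param window_radius low-pass window radius in cycles/pixel; default
#'   0.8 times the carrier magnitude, with a flat core at half the radius
#'   and a raised-cosine taper beyond it.
#' @param min_prominence peak-to-median spectral modulus ratio below which
#'   carrier detection fails.
#' @return A [phase_image()] of wrapped phase in `(-pi, pi]`.
#' @export
reconstruct_phase <- function(holo, carrier_hint = NULL, window_radius = NULL,
                              min_prominence = 5) {
  stopifnot(inherits(holo, "hologram") || is.list(holo))
  intensity <- holo$intensity
  detected <- is.null(carrier_hint) && is.null(holo$carrier)
  carrier <- carrier_hint %||% holo$carrier %||%
    detect_carrier(intensity, min_prominence)
  check_carrier(carrier)
  dm <- dim(intensity)
  x <- outer(rep(1, dm[1]), 0:(dm[2] - 1))
  y <- outer(0:(dm[1] - 1), rep(1, dm[2]))
  rr <- sqrt(outer(fft_freq(dm[1])^2, fft_freq(dm[2])^2, "+"))
  demodulate <- function(carrier) {
    cmag <- sqrt(sum(carrier^2))
    rad <- window_radius %||% (0.8 * cmag)
    a <- 0.5 * rad                               # flat core
    W <- ifelse(rr <= a, 1,
                ifelse(rr < rad,
                       0.5 * (1 + cos(pi * (rr - a) / (rad - a))), 0))
    F <- stats::fft(intensity *
                      exp(-2i * pi * (carrier[1] * x + carrier[2] * y)))
    stats::fft(F * W, inverse = TRUE)
  }
  field <- demodulate(carrier)
  if (detected) {
    # refine the bin-quantized carrier from the mean residual phase
    # gradient of the demodulated field, then demodulate once more
    N <- dm[2]; M <- dm[1]
    res_fx <- Arg(sum(field[, -1] * Conj(field[, -N]))) / (2 * pi)
    res_fy <- Arg(sum(field[-1, ] * Conj(field[-M, ]))) / (2 * pi)
    carrier <- carrier + c(res_fx, res_fy)
    check_carrier(carrier)
    field <- demodulate(carrier)
  }
  phase_image(wrap_phase(Arg(field)), holo$pixel_pitch_um)
}

# Solve the Neumann Poisson problem Laplacian(phi) = rho on the image grid
# via even mirror extension and a single 2-D FFT.
solve_poisson_neumann <- function(rho) {
  M <- nrow(rho); N <- ncol(rho)
  ext <- rbind(cbind(rho, rho[, N:1, drop = FALSE]),
               cbind(rho[M:1, , drop = FALSE], rho[M:1, N:1, drop = FALSE]))
  denom <- outer(2 * cos(pi * (0:(2 * M - 1)) / M),
                 2 * cos(pi * (0:(2 * N - 1)) / N), "+") - 4
  denom[1, 1] <- 1
  F <- stats::fft(ext) / denom
  F[1, 1] <- 0
  Re(stats::fft(F, inverse = TRUE))[1:M, 1:N] / (4 * M * N)
}

#' Unwrap a wrapped phase image
#'
#' Two-dimensional least-squares unwrapping: the discrete Laplacian of the
#' wrapped phase gradients is integrated by solving a Neumann Poisson
#' problem (via mirror-extended FFT), and the smooth least-squares surface
#' is then rounded back onto the lattice of the wrapped input, so the
#' result is congruent with the input modulo 2*pi (up to the reported
#' offset). The minimum over `background` (default: the whole image) is
#' shifted to zero.
#'
#' @param wrapped a [phase_image()] with values in `(-pi, pi]` (larger
#'   inputs are accepted and treated as already continuous).
#' @param background optional logical matrix marking a cell-free region
#'   used to anchor the zero level.
#' @return A [phase_image()] of continuous phase.
#' @export
unwrap_phase <- function(wrapped, background = NULL) {
  stopifnot(inherits(wrapped, "phase_image"))
  w <- wrapped$values
  M <- nrow(w); N <- ncol(w)
  dx <- wrap_phase(w[, -1, drop = FALSE] - w[, -N, drop = FALSE])
  dy <- wrap_phase(w[-1, , drop = FALSE] - w[-M, , drop = FALSE])
  rho <- matrix(0, M, N)
  rho[, 1:(N - 1)] <- rho[, 1:(N - 1)] + dx
  rho[, 2:N] <- rho[, 2:N] - dx
  rho[1:(M - 1), ] <- rho[1:(M - 1), ] + dy
  rho[2:M, ] <- rho[2:M, ] - dy
  ls <- solve_poisson_neumann(rho)
  u <- w + 2 * pi * round((ls - w) / (2 * pi))
  if (!is.null(background)) {
    check_mask(background, wrapped)
    u <- u - min(u[background])
  } else {
    u <- u - min(u)
  }
  phase_image(u, wrapped$pixel_pitch_um, wrapped$time_min)
}

#' Remove tilt and low-order aberrations from a phase image
#'
#' Fits a 2-D polynomial of total degree `poly_order` to the phase over a
#' cell-free region by least squares and subtracts it from the whole
#' image, so that cell-free background sits at zero as required before
#' dry-mass or thickness evaluation.
#'
#' @param img a [phase_image()].
#' @param cellfree logical matrix marking cell-free pixels; must contain
#'   at least as many pixels as the polynomial has coefficients.
#' @param poly_order total polynomial degree (0 = constant offset,
#'   1 = tilt plane, ...); default 1.
#' @return A corrected [phase_image()]; the mean over `cellfree` is zero
#'   to numerical precision.
#' @export
background_correct <- function(img, cellfree, poly_order = 1) {
  stopifnot(inherits(img, "phase_image"))
  check_mask(cellfree, img, require_nonempty = FALSE)
  n_coef <- (poly_order + 1) * (poly_order + 2) / 2
  if (sum(cellfree) < n_coef) {
    stop_units("cell-free region has ", sum(cellfree),
               " pixels but the order-", poly_order,
               " polynomial needs at least ", n_coef)
  }
  dm <- dim(img$values)
  # normalized coordinates for conditioning
  xs <- seq(-1, 1, length.out = dm[2])
  ys <- seq(-1, 1, length.out = dm[1])
  x <- outer(rep(1, dm[1]), xs)
  y <- outer(ys, rep(1, dm[2]))
  terms <- list()
  for (a in 0:poly_order) for (b in 0:(poly_order - a)) {
    terms[[length(terms) + 1]] <- as.vector(x^a * y^b)
  }
  X <- do.call(cbind, terms)
  coef <- stats::lsfit(X[cellfree, , drop = FALSE], img$values[cellfree],
                       intercept = FALSE)$coefficients
  surface <- matrix(X %*% coef, dm[1], dm[2])
  phase_image(img$values - surface, img$pixel_pitch_um, img$time_min)
}
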