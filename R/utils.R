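# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. `seed = NULL` leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

stop_units <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop_units(sprintf("`%s` must be a single finite number", name))
  }
  invisible(x)
}

# Wrap phase to (-pi, pi].
wrap_phase <- function(p) {
  w <- (p + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# FFT bin frequencies in cycles/sample for length n.
fft_freq <- function(n) {
  k <- 0:(n - 1)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k / n
}

# 0-based pixel-center coordinate grids (um) for an M x N image.
# x varies along columns, y along rows.
pixel_grid <- function(dim, pitch) {
  list(
    x = outer(rep(1, dim[1]), (0:(dim[2] - 1)) * pitch),
    y = outer((0:(dim[1] - 1)) * pitch, rep(1, dim[2]))
  )
}
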