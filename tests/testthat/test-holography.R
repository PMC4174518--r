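# Off-axis hologram simulation, sideband demodulation, unwrapping and
# background flattening.

test_that("simulated holograms have the textbook fringe structure", {
  flat <- uniform_image(0, n = 60)
  h <- simulate_hologram(flat, carrier = c(1 / 6, 0))
  # |O| = |R| = 1: I = 2 + 2 cos, so fringes span [0, 4]
  expect_equal(min(h$intensity), 0, tolerance = 1e-12)
  expect_equal(max(h$intensity), 4, tolerance = 1e-12)
  # no reference wave, no fringes
  h0 <- simulate_hologram(gaussian_field(), carrier = c(1 / 6, 0),
                          ref_amp = 0)
  expect_equal(diff(range(h0$intensity)), 0)
  expect_error(simulate_hologram(flat, carrier = c(0.5, 0)), "Nyquist")
  expect_error(simulate_hologram(flat, carrier = c(0, 0)), "magnitude")
  # seeded noise is reproducible
  h1 <- simulate_hologram(flat, c(1 / 6, 0), noise_sd = 0.1, seed = 3)
  h2 <- simulate_hologram(flat, c(1 / 6, 0), noise_sd = 0.1, seed = 3)
  expect_identical(h1$intensity, h2$intensity)
})

test_that("reconstruction recovers flat and plateau phases", {
  flat <- uniform_image(0, n = 96)
  h <- simulate_hologram(flat, carrier = c(1 / 6, 0))
  rec <- reconstruct_phase(h)
  i <- interior(rec$values)
  expect_lt(max(abs(rec$values[i$rows, i$cols])), 0.01)
  # a 1 rad plateau on zero background comes back at 1 +/- 0.02
  v <- matrix(0, 96, 96); v[, 1:48] <- 1
  h2 <- simulate_hologram(phase_image(v, 0.5), carrier = c(1 / 6, 1 / 8))
  rec2 <- reconstruct_phase(h2)
  plateau <- rec2$values[20:76, 12:36]          # away from edges and border
  expect_equal(stats::median(plateau), 1, tolerance = 0.02)
})

test_that("reconstruction is invariant to a global intensity scale", {
  h <- simulate_hologram(gaussian_field(amp = 1.5), carrier = c(1 / 6, 1 / 8))
  rec1 <- reconstruct_phase(h)
  h$intensity <- 37 * h$intensity
  rec2 <- reconstruct_phase(h)
  expect_equal(rec1$values, rec2$values, tolerance = 1e-10)
})

test_that("carrier detection finds the sideband and rejects fringe-free input", {
  img <- gaussian_field(amp = 1, pitch = 0.25, field_um = 32)
  h <- simulate_hologram(img, carrier = c(1 / 6, 1 / 8))
  h$carrier <- NULL
  rec <- reconstruct_phase(h)             # detection path
  u <- unwrap_phase(rec)
  corr <- background_correct(u, img$values < 0.05, 1)
  expect_lt(rmse_interior(corr$values, img$values), 0.05)
  h$intensity <- matrix(1, 128, 128)      # no fringes at all
  expect_error(reconstruct_phase(h), "no detectable")
})

test_that("unwrapping recovers ramps and sphere caps exactly modulo offset", {
  # an already-continuous field is returned unchanged up to a global offset
  img <- gaussian_field(amp = 2.5)
  u <- unwrap_phase(img)
  expect_equal(u$values, img$values - min(img$values), tolerance = 1e-10)
  # wrapped linear ramp 0 -> 10 rad
  n <- 128
  ramp <- outer(rep(1, n), seq(0, 10, length.out = n))
  wr <- phase_image((ramp + pi) %% (2 * pi) - pi, 0.5)
  ur <- unwrap_phase(wr)
  expect_equal(max(ur$values), 10, tolerance = 0.01)
  expect_lt(max(abs(ur$values - ramp)), 1e-6)
  # wrapped sphere cap with 7.96 rad peak
  cfg <- cfg_fine()
  sph <- make_sphere_image(11.7, 1.3678, cfg)
  ws <- phase_image((sph$values + pi) %% (2 * pi) - pi, 0.25)
  us <- unwrap_phase(ws)
  expect_equal(max(us$values), max(sph$values), tolerance = 0.05)
  expect_lt(max(abs(us$values - sph$values)), 1e-6)
})

test_that("background_correct flattens tilt and offset", {
  n <- 64
  tilt <- outer(seq(0, 2, length.out = n), seq(-1, 1, length.out = n), "+")
  img <- phase_image(tilt, 0.5)
  out <- background_correct(img, matrix(TRUE, n, n), poly_order = 1)
  expect_lt(max(abs(out$values)), 1e-8)
  # order 0 removes a constant offset
  out0 <- background_correct(uniform_image(0.7), matrix(TRUE, 20, 20), 0)
  expect_lt(max(abs(out0$values)), 1e-10)
  # sphere on a tilted background, fitted on the cell-free complement
  cfg <- cfg_fine()
  sph <- make_sphere_image(7.2, 1.3713, cfg)
  nn <- dim(sph$values)
  plane <- outer(seq(0, 0.8, length.out = nn[1]),
                 seq(0, 0.5, length.out = nn[2]), "+")
  noisy <- phase_image(sph$values + plane, 0.25)
  cellfree <- sph$values == 0
  out2 <- background_correct(noisy, cellfree, 1)
  expect_lt(abs(mean(out2$values[cellfree])), 0.01)
  expect_equal(max(out2$values), max(sph$values), tolerance = 0.01)
  expect_error(background_correct(img, matrix(FALSE, n, n), 1), "cell-free")
})

test_that("simulate-reconstruct-unwrap round trip meets tolerance", {
  # a sharp-edged sphere footprint at a comfortable carrier
  cfg <- cfg_fine()
  img <- make_sphere_image(9.1, 1.3707, cfg, field_um = c(64, 64))
  h <- simulate_hologram(img, c(1 / 6, 1 / 8))
  u <- unwrap_phase(reconstruct_phase(h))
  corr <- background_correct(u, img$values == 0, 1)
  expect_lt(rmse_interior(corr$values, img$values), 0.05)
  # a smooth field down to the 1/8 cycles/pixel carrier
  smooth <- gaussian_field(amp = 2, sigma_um = 8, field_um = 48)
  for (carrier in list(c(1 / 8, 0), c(1 / 8, 1 / 8))) {
    hs <- simulate_hologram(smooth, carrier)
    us <- unwrap_phase(reconstruct_phase(hs))
    cs <- background_correct(us, smooth$values < 0.05, 1)
    expect_lt(rmse_interior(cs$values, smooth$values), 0.05)
  }
})

test_that("round-trip error grows monotonically with hologram noise", {
  img <- gaussian_field(amp = 2, pitch = 0.5, field_um = 48)
  rmse_at <- vapply(c(0.05, 0.2, 0.6), function(sd) {
    h <- simulate_hologram(img, c(1 / 6, 1 / 8), noise_sd = sd, seed = 9)
    u <- unwrap_phase(reconstruct_phase(h))
    corr <- background_correct(u, img$values < 0.05, 1)
    rmse_interior(corr$values, img$values)
  }, numeric(1))
  expect_true(all(diff(rmse_at) > 0))
})
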