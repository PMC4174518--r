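# Frame metrics, relative series, cell-number estimates, rate constants
# and thickness profiles.

test_that("frame metrics reproduce the closed forms and their identity", {
  cfg <- cfg_default()
  img <- uniform_image(3.814791, time = 0)     # 10 um at n_cell = 1.3713
  m <- full_mask(img)                          # 100 um^2
  fm <- compute_frame_metrics(img, m, 1.3713, cfg)
  expect_equal(fm$S_c_um2, 100)
  expect_equal(fm$d_mean_um, 10, tolerance = 1e-6)
  expect_equal(fm$volume_um3, 1000, tolerance = 1e-6)
  expect_equal(fm$dry_mass_pg, 161.5, tolerance = 1e-3)
  # empty mask: a valid all-zero observation
  fm0 <- compute_frame_metrics(img, m & FALSE, 1.3713, cfg)
  expect_equal(unlist(fm0[c("S_c_um2", "dry_mass_pg", "d_mean_um",
                            "volume_um3")], use.names = FALSE),
               c(0, 0, 0, 0))
  # DM = Dn * V / alpha holds frame-wise at machine precision
  set.seed(17)
  for (i in 1:5) {
    imr <- phase_image(matrix(runif(400, 0, 4), 20, 20), 0.5)
    mr <- matrix(runif(400) > 0.4, 20, 20)
    f <- compute_frame_metrics(imr, mr, 1.3713, cfg)
    expect_equal(f$dry_mass_pg, sphere_dry_mass(f$volume_um3, 1.3713, cfg))
    expect_equal(f$volume_um3, f$S_c_um2 * f$d_mean_um)
  }
})

test_that("relative series subtract the first frame only for area and mass", {
  t <- seq(0, 2400, by = 30)
  frames <- data.frame(time_min = t, S_c_um2 = 5000, dry_mass_pg = 100,
                       d_mean_um = 4, volume_um3 = 20000)
  rs <- relative_series(frames)
  expect_equal(rs$dS_c_um2, rep(0, length(t)))
  expect_equal(rs$dDM_pg, rep(0, length(t)))
  # linear mass growth at 18.3 pg/min accumulates 43,920 pg over 40 h
  frames$dry_mass_pg <- 100 + 18.3 * t
  rs2 <- relative_series(frames)
  expect_equal(rs2$dDM_pg[1], 0)
  expect_equal(rs2$dDM_pg[length(t)], 18.3 * 2400)
  expect_error(relative_series(frames[c(3, 1, 2), ]), "time-ordered")
  expect_error(relative_series(frames[1, ]), "at least two")
})

test_that("cell number is the dry-mass quotient with sign semantics", {
  # printed control values: 23.9 ng accumulated / 265 pg per cell
  expect_equal(estimate_cell_number(23900, 265), 90.2, tolerance = 1e-3)
  expect_equal(estimate_cell_number(0, 265), 0)
  expect_warning(n <- estimate_cell_number(-530, 265), "mass loss")
  expect_equal(n, -2)
  expect_error(estimate_cell_number(100, 0), "> 0")
})

test_that("rate estimation recovers exact and noisy linear trends", {
  t <- seq(0, 2400, by = 30)
  exact <- data.frame(time_min = t, S_c_um2 = 1000 + 23.1 * t)
  r <- estimate_rates(exact, metrics = "S_c_um2")
  expect_equal(r$slope, 23.1, tolerance = 1e-9)
  expect_lt(r$se, 1e-9)
  expect_equal(r$units, "um2/min")
  set.seed(23)
  noisy <- data.frame(time_min = t,
                      S_c_um2 = 1000 + 23.1 * t + rnorm(length(t), sd = 400))
  rn <- estimate_rates(noisy, metrics = "S_c_um2")
  expect_lt(abs(rn$slope - 23.1), 2 * rn$se)
  # a constant series has slope zero
  rc <- estimate_rates(data.frame(time_min = t, volume_um3 = 5),
                       metrics = "volume_um3")
  expect_equal(rc$slope, 0)
  expect_error(estimate_rates(exact[1:2, ], "S_c_um2"), "at least 3")
})

test_that("thickness slopes are reported in nm/min", {
  t <- seq(0, 2400, by = 30)
  d <- data.frame(time_min = t, d_mean_um = 4 + 0.51e-3 * t)  # 0.51 nm/min
  r <- estimate_rates(d, metrics = "d_mean_um")
  expect_equal(r$slope, 0.51, tolerance = 1e-9)
  expect_equal(r$units, "nm/min")
})

test_that("rates transform exactly under a time-unit rescale", {
  t <- seq(0, 2400, by = 30)
  set.seed(5)
  y <- 1000 + 23.1 * t + rnorm(length(t), sd = 100)
  per_min <- estimate_rates(data.frame(time_min = t, S_c_um2 = y), "S_c_um2")
  per_hr <- estimate_rates(data.frame(time_min = t / 60, S_c_um2 = y),
                           "S_c_um2")
  expect_equal(per_hr$slope, 60 * per_min$slope)
  expect_equal(per_hr$se, 60 * per_min$se)
})

test_that("replicates are averaged on a common grid before regression", {
  t <- seq(0, 600, by = 30)
  reps <- lapply(c(-50, 0, 50), function(off) {
    data.frame(time_min = t, S_c_um2 = 1000 + off + 10 * t)
  })
  r <- estimate_rates(reps, metrics = "S_c_um2")
  expect_equal(r$slope, 10, tolerance = 1e-9)
  expect_equal(r$n_replicates, 3)
  bad <- reps
  bad[[2]]$time_min <- bad[[2]]$time_min + 1
  expect_error(estimate_rates(bad, "S_c_um2"), "grids mismatch")
})

test_that("thickness profiles trace plateaus, wedges and wound gaps", {
  cfg <- cfg_default()
  img <- uniform_image(3.814791, n = 40)
  prof <- thickness_profile(img, 1.3713, cfg)
  expect_equal(prof$thickness_um, rep(10, 40), tolerance = 1e-6)
  # planted linear wedge 0 -> 10 um along x
  d_line <- seq(0, 10, length.out = 40)
  wedge <- phase_image(outer(rep(1, 40),
                             phase_from_thickness(d_line, 1.3713, cfg)), 0.5)
  pw <- thickness_profile(wedge, 1.3713, cfg)
  expect_equal(pw$thickness_um[1], 0, tolerance = 1e-9)
  expect_lt(abs(pw$thickness_um[40] - 10) / 10, 0.02)
  # a wound frame dips to zero inside the gap
  spec <- assay_spec(field_um = c(200, 60), gap_start_um = 60,
                     gap_end_um = 140, front_speed = c(left = 0, right = 0),
                     n_frames = 2)
  assay <- make_wound_assay(spec, cfg)
  pg <- thickness_profile(assay$stack[[1]], 1.3713, cfg)
  mid <- pg$position_um > 80 & pg$position_um < 120
  expect_equal(pg$thickness_um[mid], rep(0, sum(mid)))
  expect_error(thickness_profile(img, 1.3713, cfg,
                                 band = matrix(FALSE, 40, 40)), "empty")
})
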