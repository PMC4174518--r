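# Synthetic-data generators: planted parameters must be recorded
# faithfully and reproducibly.

test_that("sphere images realise the closed-form peak and determinism", {
  cfg <- cfg_fine()
  img <- make_sphere_image(11.7, 1.3678, cfg)
  expect_equal(max(img$values), 7.96, tolerance = 1e-3)
  # index-matched sphere vanishes
  img0 <- make_sphere_image(5, 1.339, cfg)
  expect_equal(max(abs(img0$values)), 0)
  # same seed, bit-identical noise
  a <- make_sphere_image(5, 1.36, cfg, noise_sd = 0.05, seed = 4)
  b <- make_sphere_image(5, 1.36, cfg, noise_sd = 0.05, seed = 4)
  expect_identical(a$values, b$values)
  expect_error(make_sphere_image(10, 1.36, cfg, center_um = c(3, 20),
                                 field_um = c(40, 40)), "clipped")
})

test_that("population draws respect their spec and truncation bounds", {
  cfg <- cfg_default()
  spec <- sphere_population_spec(n_cells = 89, seed = 11)
  pop <- make_sphere_population(spec, cfg)
  expect_equal(nrow(pop$truth), 89)
  # CLT bound on the sample mean of the generator itself
  expect_lt(abs(mean(pop$truth$radius_um) - 7.2), 2 * 1.2 / sqrt(89))
  expect_true(all(pop$truth$radius_um > 1))
  expect_true(all(pop$truth$n_cell > cfg$n_medium + 0.001))
  # degenerate SDs give identical cells
  spec0 <- sphere_population_spec(n_cells = 5, radius_sd_um = 0,
                                  n_cell_sd = 0, noise_sd = 0, seed = 1)
  pop0 <- make_sphere_population(spec0, cfg)
  expect_equal(length(unique(pop0$truth$radius_um)), 1L)
  expect_identical(pop0$images[[1]]$values, pop0$images[[5]]$values)
  # truth is self-consistent with the closed-form mass relation
  expect_equal(pop$truth$dry_mass_pg,
               (pop$truth$n_cell - cfg$n_medium) * pop$truth$volume_um3 /
                 cfg$alpha_um3_per_pg)
})

test_that("wound-assay truth follows the planted linear dynamics", {
  cfg <- cfg_default()
  spec <- assay_spec(field_um = c(300, 110), gap_start_um = 50,
                     gap_end_um = 250, front_speed = c(left = 0.21, right = 0),
                     n_frames = 10)
  assay <- make_wound_assay(spec, cfg)
  expect_equal(diff(assay$truth$area_um2), rep(693, 9), tolerance = 1e-9)
  # internally consistent via the closed forms, every frame
  expect_equal(assay$truth$dry_mass_pg,
               sphere_dry_mass(assay$truth$volume_um3, 1.3713, cfg))
  expect_equal(assay$truth$volume_um3,
               assay$truth$area_um2 * assay$truth$d_mean_um)
  # static spec (no motion, no thickening): all frames identical
  spec0 <- assay_spec(field_um = c(150, 50), gap_start_um = 40,
                      gap_end_um = 110, front_speed = c(left = 0, right = 0),
                      thickness_rate_nm_per_min = c(left = 0, right = 0),
                      n_frames = 3)
  a0 <- make_wound_assay(spec0, cfg)
  expect_identical(a0$stack[[1]]$values, a0$stack[[3]]$values)
  # fronts crossing mid-gap are a spec error
  expect_error(assay_spec(field_um = c(150, 50), gap_start_um = 40,
                          gap_end_um = 110,
                          front_speed = c(left = 1, right = 1),
                          n_frames = 10),
               "collide")
})

test_that("assay generation is bit-reproducible under a fixed seed", {
  cfg <- cfg_default()
  spec <- assay_spec(field_um = c(150, 50), gap_start_um = 40,
                     gap_end_um = 110, front_speed = c(left = 0.2, right = 0.1),
                     n_frames = 4, noise_sd = 0.05, seed = 77)
  a1 <- make_wound_assay(spec, cfg)
  a2 <- make_wound_assay(spec, cfg)
  for (k in seq_along(a1$stack)) {
    expect_identical(a1$stack[[k]]$values, a2$stack[[k]]$values)
  }
  expect_identical(a1$truth, a2$truth)
})

test_that("segmentation recovers the planted coverage of assay frames", {
  cfg <- cfg_default()
  spec <- assay_spec(field_um = c(300, 110), gap_start_um = 50,
                     gap_end_um = 250,
                     front_speed = c(left = 0.3, right = 0.2),
                     noise_sd = 0.05, n_frames = 6, seed = 3)
  assay <- make_wound_assay(spec, cfg)
  cov <- gap_coverage_series(assay$stack, assay$geometry)
  # pixel-centre rasterization biases each front edge by at most one
  # pixel column; per-frame gains are free of that constant bias
  height_um <- 110
  expect_lt(max(abs(cov$S_c_um2[-1] - assay$truth$area_um2[-1])),
            1.5 * 0.5 * height_um * 2)
  expect_equal(diff(cov$S_c_um2), diff(assay$truth$area_um2),
               tolerance = 0.02)
})

test_that("hologram encoding is reproducible and demodulates back", {
  cfg <- cfg_default()
  # a thin layer: spectral ringing at the step fronts scales with the
  # plateau phase, and the 0.05 rad whole-frame bound needs a small step
  spec <- assay_spec(field_um = c(128, 64), gap_start_um = 40,
                     gap_end_um = 90, front_speed = c(left = 0.2, right = 0),
                     thickness0_um = c(left = 2, right = 2),
                     n_frames = 3)
  assay <- make_wound_assay(spec, cfg)
  holos <- encode_assay_holograms(assay$stack, carrier = c(1 / 6, 1 / 8),
                                  noise_sd = 0.01, seed = 12)
  holos2 <- encode_assay_holograms(assay$stack, carrier = c(1 / 6, 1 / 8),
                                   noise_sd = 0.01, seed = 12)
  for (k in seq_along(holos)) {
    expect_identical(holos[[k]]$intensity, holos2[[k]]$intensity)
  }
  # zero-phase stack gives identical fringe frames
  flat <- list(uniform_image(0, 48), uniform_image(0, 48))
  hf <- encode_assay_holograms(flat, carrier = c(1 / 6, 0))
  expect_identical(hf[[1]]$intensity, hf[[2]]$intensity)
  # frame-wise round trip within tolerance
  for (k in seq_along(holos)) {
    u <- unwrap_phase(reconstruct_phase(holos[[k]]))
    corr <- background_correct(u, assay$stack[[k]]$values == 0, 1)
    expect_lt(rmse_interior(corr$values, assay$stack[[k]]$values), 0.05)
  }
  # at a thicker layer the plateau interior is still recovered accurately
  spec3 <- assay_spec(field_um = c(128, 64), gap_start_um = 40,
                      gap_end_um = 90, front_speed = c(left = 0, right = 0),
                      thickness0_um = c(left = 3, right = 3), n_frames = 2)
  a3 <- make_wound_assay(spec3, cfg)
  h3 <- simulate_hologram(a3$stack[[1]], c(1 / 6, 1 / 8))
  u3 <- unwrap_phase(reconstruct_phase(h3))
  c3 <- background_correct(u3, a3$stack[[1]]$values == 0, 1)
  plateau <- a3$stack[[1]]$values > 0
  plateau[, 70:190] <- FALSE                    # keep clear of the fronts
  level <- max(a3$stack[[1]]$values)
  expect_lt(abs(stats::median(c3$values[plateau]) - level), 0.02)
})
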