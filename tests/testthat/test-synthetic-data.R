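test_that("particle image generator handles the empty and single-disk cases", {
  out <- generate_particle_image(list(), c(32, 32), 0.5, seed = 1)
  expect_equal(nrow(out$truth), 0L)
  expect_true(all(unclass(out$image) == 0.1))

  out <- generate_particle_image(list(shape_disk(c(16, 16), 10)),
                                 c(32, 32), pixel_size = 0.5, seed = 1)
  expect_equal(out$truth$equiv_diameter_um, 10)   # 2 * 10 px * 0.5 um/px
  expect_equal(out$truth$circularity, 1)
  expect_equal(out$truth$solidity, 1)
  expect_equal(out$truth$inv_aspect_ratio, 1)
})

test_that("generator rejects overlapping and out-of-frame shapes", {
  expect_error(generate_particle_image(list(shape_disk(c(10, 10), 8),
                                            shape_disk(c(14, 10), 8)),
                                       c(32, 32), 0.5),
               "overlaps")
  expect_error(generate_particle_image(list(shape_disk(c(3, 16), 8)),
                                       c(32, 32), 0.5),
               "outside the image frame")
})

test_that("generators are bit-identical under a repeated seed", {
  a <- generate_particle_image(list(shape_disk(c(16, 16), 8)), c(32, 32),
                               0.5, noise_sd = 0.05, seed = 7)
  b <- generate_particle_image(list(shape_disk(c(16, 16), 8)), c(32, 32),
                               0.5, noise_sd = 0.05, seed = 7)
  expect_identical(a$image, b$image)

  t1 <- generate_prw_trajectory(10, 5, 5, 50, seed = 3)
  t2 <- generate_prw_trajectory(10, 5, 5, 50, seed = 3)
  expect_identical(t1, t2)

  z <- seq(-5e-7, 1e-6, length.out = 100)
  h1 <- generate_hertz_curve(1e3, 0.45, 30e-9, 0, z, noise_sd = 1e-11, seed = 5)
  h2 <- generate_hertz_curve(1e3, 0.45, 30e-9, 0, z, noise_sd = 1e-11, seed = 5)
  expect_identical(h1, h2)

  mask <- make_cell_mask(c(200, 200), c(80, 60), 0.1)
  f1 <- generate_fa_image(mask, 5, function(n) runif(n, 5, 8), seed = 9)
  f2 <- generate_fa_image(mask, 5, function(n) runif(n, 5, 8), seed = 9)
  expect_identical(f1$marker, f2$marker)
  expect_identical(f1$truth, f2$truth)
})

test_that("bead diameters follow the manufacturer distribution", {
  gen <- generate_bead_image(300, seed = 21)
  sem <- 1.01 / sqrt(300)
  expect_lt(abs(mean(gen$truth$diameter_um) - 9.94), 3 * sem)
  expect_true(all(gen$truth$diameter_um > 0))
})

test_that("a zero-diffusivity walk never moves and tau/dt are validated", {
  tr <- generate_prw_trajectory(0, 5, 5, 20, seed = 1)
  expect_true(all(tr$x_um == 0) && all(tr$y_um == 0))
  expect_error(generate_prw_trajectory(10, 0, 5, 20), "tau")
  expect_error(generate_prw_trajectory(10, 5, -1, 20), "dt")
})

test_that("ensemble MSD of generated walks matches the Fuerth form", {
  D <- 10; tau <- 5; dt <- 5
  ens <- generate_prw_ensemble(500, D, tau, dt, n_steps = 100, seed = 100)
  tracks <- split(ens, ens$track_id)
  curves <- lapply(tracks, compute_msd, max_lag_fraction = 0.5)
  lags <- curves[[1]]$lag_min
  keep <- lags <= 20 * tau
  per_track <- sapply(curves, `[[`, "msd_um2")[keep, ]
  obs <- rowMeans(per_track)
  se <- apply(per_track, 1, sd) / sqrt(ncol(per_track))
  expected <- furth_msd(lags[keep], D, tau)
  expect_true(all(abs(obs - expected) <= 3 * se))
})

test_that("Hertz curve generator matches the closed form and its noise spec", {
  z <- seq(-1e-6, 1e-6, length.out = 200)
  fc <- generate_hertz_curve(1e3, 0.45, 30e-9, 0, z, noise_sd = 0)
  expect_true(all(fc$force_N[fc$z_m < 0] == 0))
  expect_equal(fc$force_N[fc$z_m > 0],
               hertz_force(1e3, 0.45, 30e-9, fc$z_m[fc$z_m > 0]))

  zb <- seq(-2e-6, -1e-6, length.out = 1000)   # all pre-contact
  fb <- generate_hertz_curve(1e3, 0.45, 30e-9, 0, zb, noise_sd = 1e-11,
                             seed = 4)
  expect_lt(abs(sd(fb$force_N) - 1e-11) / 1e-11, 0.10)

  expect_error(generate_hertz_curve(1e3, 0.45, 30e-9, 0, c(0, 1e-7, 5e-8)),
               "increasing")
})

test_that("FA image generator books its ground truth correctly", {
  mask <- make_cell_mask(c(300, 300), c(120, 90), 0.1)
  blank <- generate_fa_image(mask, 0, numeric(0))
  expect_equal(nrow(blank$truth), 0L)
  expect_true(all(unclass(blank$marker)[unclass(mask)] == 0.05))

  ten <- generate_fa_image(mask, 10, function(n) runif(n, 5, 9), seed = 2)
  expect_equal(nrow(ten$truth), 10L)
  expect_false(any(ten$truth$below_min))

  # areas straddling the 4.14 um^2 cutoff: flags follow pixel-count areas
  strad <- generate_fa_image(mask, 8, seq(2.5, 6, length.out = 8), seed = 5)
  expect_equal(strad$truth$below_min, strad$truth$area_um2 < 4.14)
  expect_true(any(strad$truth$below_min) && any(!strad$truth$below_min))

  tiny <- make_cell_mask(c(40, 40), c(12, 10), 0.1)
  expect_error(generate_fa_image(tiny, 30, rep(6, 30), seed = 1),
               "too small")
})

test_that("rendered noiseless shapes close the loop with the morphometry module", {
  # generator/analysis closure: measured area within 2% of truth for
  # disks with radius >= 15 px
  for (r in c(15, 20, 28)) {
    out <- generate_particle_image(list(shape_disk(c(40, 40), r)),
                                   c(96, 96), 0.4, seed = 1)
    rec <- shape_descriptors(segment_particles(out$image))
    expect_lt(abs(rec$area_um2 - out$truth$area_um2) / out$truth$area_um2,
              0.02)
  }
})
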