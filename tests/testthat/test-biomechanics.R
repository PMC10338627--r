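test_that("MSD matches closed forms and the naive double-loop oracle", {
  # stationary beads
  still <- list(time = seq(0, 4, by = 1), x = matrix(0, 5, 3),
                y = matrix(0, 5, 3))
  expect_true(all(compute_msd(still, max_lag = 3)$msd == 0))

  # ballistic bead: (1, 0) nm per frame -> msd(k dt) = k^2
  ball <- list(time = 0:9, x = matrix(0:9, 10, 1), y = matrix(0, 10, 1))
  msd <- compute_msd(ball, max_lag = 4)
  expect_equal(msd$msd, c(0, (1:4)^2))

  bt <- simulate_bead_tracks(bead_sim_config(n_beads = 5, duration = 4,
                                             frame_rate = 12, seed = 2))
  msd2 <- compute_msd(bt, max_lag = 2)
  for (k in c(1L, 5L, 20L)) {
    expect_equal(msd2$msd[k + 1],
                 oracle_msd(bt$x, bt$y, k), tolerance = 1e-9)
  }
  expect_error(compute_msd(bt, max_lag = 100), "bounds")
})

test_that("diffusion coefficient is recovered from Brownian tracks with a near-linear MSD", {
  bt <- simulate_bead_tracks(bead_sim_config(n_beads = 400, duration = 30,
                                             diffusion_coefficient = 2500,
                                             seed = 8))
  msd <- compute_msd(bt, max_lag = 5)
  fit <- fit_diffusion(msd)
  expect_lt(abs(fit$D - 2500) / 2500, 0.1)
  expect_gt(fit$r_squared, 0.99)
})

test_that("Hertz fit recovers the modulus exactly on noiseless curves and is scale-equivariant", {
  fc <- simulate_force_curve(hertz_sim_config(youngs_modulus_true = 1000))
  fit <- fit_hertz(fc)
  expect_equal(fit$youngs_modulus, 1000, tolerance = 1e-9)
  expect_equal(unname(coef(fit)), 1000, tolerance = 1e-9)
  expect_equal(predict(fit, newdata = 1e-6),
               fc$force[length(fc$force)], tolerance = 1e-9)

  # force scaling: E -> c E; indentation scaling: E -> E / c^2
  fc_f <- force_curve(fc$indentation, 3 * fc$force)
  expect_equal(fit_hertz(fc_f)$youngs_modulus, 3000, tolerance = 1e-9)
  fc_d <- force_curve(2 * fc$indentation, fc$force)
  expect_equal(fit_hertz(fc_d)$youngs_modulus, 250, tolerance = 1e-9)

  expect_error(fit_hertz(force_curve(rep(0, 5), rep(0, 5))), "degenerate")
  expect_error(force_curve(c(0, 1e-7), c(0, 1e-10), poisson_ratio = 1),
               "poisson_ratio")
})

test_that("single-point closed-form inversion agrees with the contact relation", {
  e <- hertz_point_modulus(1e-6, 5.94e-10, tip_half_angle = 35,
                           poisson_ratio = 0.5)
  expect_equal(e, 1000, tolerance = 1e-3)
})

test_that("Hertz estimates from noisy curves are unbiased within 2% over replicates", {
  e_hat <- vapply(1:300, function(i) {
    cfg <- hertz_sim_config(youngs_modulus_true = 1000,
                            force_noise_sd = 0.05 * 5.94e-10, seed = i)
    fit_hertz(simulate_force_curve(cfg))$youngs_modulus
  }, numeric(1))
  expect_lt(abs(mean(e_hat) - 1000) / 1000, 0.02)
})

test_that("contact-point estimation recovers a known offset and flags pure noise", {
  d0_true <- 50e-9
  z <- seq(0, 1e-6, length.out = 400)
  pref <- 2 * 800 * tan(35 * pi / 180) / (pi * 0.75)
  f <- ifelse(z > d0_true, pref * (z - d0_true)^2, 0)
  set.seed(17)
  f <- f + rnorm(length(f), 0, 1e-12)
  est <- estimate_contact_point(z, f)
  expect_true(est$contact_found)
  expect_lt(abs(est$offset - d0_true), 5e-9)
  refit <- fit_hertz(est$curve)
  expect_lt(abs(refit$youngs_modulus - 800) / 800, 0.05)

  # zero offset
  f0 <- pref * z^2 + rnorm(length(z), 0, 1e-12)
  est0 <- estimate_contact_point(z, f0)
  expect_true(est0$contact_found)
  expect_lt(est0$offset, 6e-9)

  # pure noise: no detectable contact
  noise <- rnorm(length(z), 0, 1e-11)
  estn <- estimate_contact_point(z, noise)
  expect_false(estn$contact_found)
  expect_null(estn$curve)
})

test_that("MTC stiffness is the amplitude ratio, phase-invariant, and scales inversely with displacement", {
  t <- seq(0, 50, by = 0.01)
  w <- 2 * pi * 0.75
  for (phi in c(0, 0.8, 2.9)) {
    rec <- twisting_record(t, 10 * sin(w * t), 5 * sin(w * t - phi),
                           driving_frequency = 0.75)
    res <- mtc_stiffness(rec)
    expect_equal(res$stiffness, 2, tolerance = 1e-9)
  }
  rec2 <- twisting_record(t, 10 * sin(w * t), 10 * sin(w * t - 0.4),
                          driving_frequency = 0.75)
  expect_equal(mtc_stiffness(rec2)$stiffness, 1, tolerance = 1e-9)

  short <- twisting_record(seq(0, 1, by = 0.01), sin(seq(0, 1, by = 0.01)),
                           sin(seq(0, 1, by = 0.01)), driving_frequency = 1)
  expect_error(mtc_stiffness(short), "2 full periods")
  flatrec <- twisting_record(t, 10 * sin(w * t), rep(0, length(t)),
                             driving_frequency = 0.75)
  expect_error(mtc_stiffness(flatrec), "unmeasurable")
})

test_that("MTC stiffness estimates stay within 2% under additive white noise", {
  t <- seq(0, 50, by = 0.02)  # ~50 periods at 1 Hz
  w <- 2 * pi
  set.seed(14)
  ests <- vapply(1:50, function(i) {
    tq <- 8 * sin(w * t + 0.2) + rnorm(length(t), 0, 0.8)
    dp <- 4 * sin(w * t - 0.9) + rnorm(length(t), 0, 0.4)
    mtc_stiffness(twisting_record(t, tq, dp, 1))$stiffness
  }, numeric(1))
  expect_lt(abs(mean(ests) - 2) / 2, 0.02)
})
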