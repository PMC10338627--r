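test_that("invalid migration configs name the offending field", {
  expect_error(migration_sim_config(n_cells = 0), "n_cells")
  expect_error(migration_sim_config(10, n_frames = 1), "n_frames")
  expect_error(migration_sim_config(10, frame_interval = 0), "frame_interval")
  expect_error(migration_sim_config(10, persistence = 1), "persistence")
  expect_error(migration_sim_config(10, drift_bias = 1.2), "drift_bias")
  expect_error(migration_sim_config(10, gradient_axis = c(0, 0)),
               "gradient_axis")
})

test_that("fully biased noiseless walks are straight lines up the gradient", {
  cfg <- migration_sim_config(n_cells = 5, n_frames = 10, drift_bias = 1,
                              persistence = 0, step_speed_sd = 0,
                              gradient_axis = c(1, 0), seed = 3)
  set <- simulate_trajectories(cfg)
  for (tr in set$trajectories) {
    expect_equal(directness(tr), 1, tolerance = 1e-12)
    expect_equal(diff(tr$y), rep(0, 9), tolerance = 1e-12)
    expect_true(all(diff(tr$x) > 0))
  }
})

test_that("trajectory generation is deterministic and prefix-stable in n_cells", {
  cfg <- migration_sim_config(n_cells = 8, drift_bias = 0.3, seed = 11)
  a <- simulate_trajectories(cfg)
  b <- simulate_trajectories(cfg)
  expect_identical(a, b)
  cfg_big <- migration_sim_config(n_cells = 12, drift_bias = 0.3, seed = 11)
  big <- simulate_trajectories(cfg_big)
  expect_identical(a$trajectories, big$trajectories[1:8])
})

test_that("simulated walks match an independent re-implementation of the update rule", {
  cfg <- migration_sim_config(n_cells = 25, n_frames = 20, drift_bias = 0.5,
                              persistence = 0.3, seed = 7)
  set <- simulate_trajectories(cfg)
  seeds <- oracle_stream_seeds(7, 25)
  for (i in c(1, 7, 25)) {
    xy <- oracle_walk_cell(seeds[i], 20, cfg$frame_interval,
                           cfg$step_speed_mean, cfg$step_speed_sd,
                           cfg$persistence, cfg$drift_bias,
                           cfg$gradient_axis)
    expect_equal(set$trajectories[[i]]$x, unname(xy[, "x"]))
    expect_equal(set$trajectories[[i]]$y, unname(xy[, "y"]))
  }
})

test_that("unbiased walks have cohort FMI within 3 standard errors of zero", {
  cfg <- migration_sim_config(n_cells = 500, drift_bias = 0, seed = 19)
  fmi <- forward_migration_indices(simulate_trajectories(cfg))
  se_par <- sd(fmi$cells$fmi_parallel) / sqrt(fmi$n_used)
  se_perp <- sd(fmi$cells$fmi_perpendicular) / sqrt(fmi$n_used)
  expect_lt(abs(fmi$fmi_parallel), 3 * se_par)
  expect_lt(abs(fmi$fmi_perpendicular), 3 * se_perp)
})

test_that("generated trajectories satisfy the triangle inequality", {
  cfg <- migration_sim_config(n_cells = 50, drift_bias = 0.2, seed = 23)
  for (tr in simulate_trajectories(cfg)$trajectories) {
    expect_lte(euclidean_distance(tr), accumulated_distance(tr) + 1e-12)
  }
})

test_that("bead tracks with D = 0 never move and have zero MSD", {
  bt <- simulate_bead_tracks(bead_sim_config(n_beads = 5, duration = 5,
                                             diffusion_coefficient = 0,
                                             seed = 1))
  expect_true(all(bt$x == 0) && all(bt$y == 0))
  msd <- compute_msd(bt, max_lag = 2)
  expect_true(all(msd$msd == 0))
})

test_that("Brownian bead MSD at 1 s matches 4 D t within 5% at n = 1000", {
  bt <- simulate_bead_tracks(bead_sim_config(n_beads = 1000, duration = 5,
                                             diffusion_coefficient = 2500,
                                             seed = 5))
  msd <- compute_msd(bt, max_lag = 1.2)
  at1 <- msd$msd[which.min(abs(msd$lag - 1))]
  expect_lt(abs(at1 - 10000) / 10000, 0.05)
})

test_that("anomalous-exponent tracks recover the log-log MSD slope", {
  bt <- simulate_bead_tracks(bead_sim_config(n_beads = 150, duration = 20,
                                             frame_rate = 6,
                                             diffusion_coefficient = 2000,
                                             anomalous_exponent = 0.5,
                                             seed = 9))
  fit <- fit_diffusion(compute_msd(bt, max_lag = 5))
  expect_lt(abs(fit$loglog_slope - 0.5), 0.05)
})

test_that("bead generation is deterministic and rejects negative D", {
  cfg <- bead_sim_config(n_beads = 3, duration = 2, seed = 4)
  expect_identical(simulate_bead_tracks(cfg), simulate_bead_tracks(cfg))
  expect_error(bead_sim_config(diffusion_coefficient = -1),
               "diffusion_coefficient")
})

test_that("synthetic force curves follow the conical-tip contact relation", {
  cfg <- hertz_sim_config(youngs_modulus_true = 1000, tip_half_angle = 35,
                          poisson_ratio = 0.5, max_indentation = 1e-6,
                          force_noise_sd = 0)
  fc <- simulate_force_curve(cfg)
  # direct substitution at delta = 1 um
  pref <- 2 * 1000 * tan(35 * pi / 180) / (pi * (1 - 0.25))
  expect_equal(fc$force[length(fc$force)], pref * 1e-12, tolerance = 1e-12)
  expect_equal(fc$force[length(fc$force)], 5.94e-10, tolerance = 1e-3)

  zero <- simulate_force_curve(hertz_sim_config(youngs_modulus_true = 0))
  expect_true(all(zero$force == 0))

  noisy <- hertz_sim_config(force_noise_sd = 1e-11, seed = 12)
  expect_identical(simulate_force_curve(noisy), simulate_force_curve(noisy))
  expect_error(hertz_sim_config(poisson_ratio = 1), "poisson_ratio")
})

test_that("synthetic Ct tables encode the requested fold change", {
  expect_equal(delta_delta_ct(simulate_ct_table(1, 4, 0))$fold_change, 1)
  tab16 <- simulate_ct_table(16, 3, 0)
  res <- delta_delta_ct(tab16)
  expect_equal(res$replicates$ddct, rep(-4, 3))
  expect_equal(res$fold_change, 16)
  expect_error(simulate_ct_table(0, 3, 0), "fold_change_true")
})

test_that("noisy Ct tables recover the true fold within the Monte-Carlo interval", {
  folds <- vapply(1:200, function(i) {
    delta_delta_ct(simulate_ct_table(3.5, 6, 0.2, seed = i))$fold_change
  }, numeric(1))
  lf <- log2(folds)
  ci <- mean(lf) + c(-1, 1) * 3 * sd(lf) / sqrt(length(lf))
  expect_gt(log2(3.5), ci[1])
  expect_lt(log2(3.5), ci[2])
})
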