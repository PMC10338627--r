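#' Configuration for the biased persistent random-walk generator
#'
#' Defines the ground truth for synthetic single-cell trajectories emulating
#' a 24-h time lapse sampled every 30 min.  Each step direction is the angle
#' of a weighted resultant of three unit vectors: the previous heading
#' (weight `persistence`), the gradient axis (weight `drift_bias`), and a
#' uniformly random noise direction (weight `1 - persistence - drift_bias`,
#' floored at 0).  Step lengths are zero-truncated Gaussian speeds times the
#' frame interval.
#'
#' @param n_cells Number of cells to simulate.
#' @param n_frames Frames per trajectory (default 49: 24 h at 30-min
#'   cadence).
#' @param frame_interval Minutes between frames (default 30).
#' @param step_speed_mean,step_speed_sd Mean and SD of per-step speed in
#'   micrometres per minute before zero-truncation.
#' @param persistence Direction correlation weight in `[0, 1)`.
#' @param drift_bias Gradient attraction weight in `[0, 1]`; 0 gives an
#'   unbiased walk, 1 (with `persistence` 0) a straight march up-gradient.
#' @param gradient_axis 2-vector, normalized internally; points from the 0%
#'   toward the 20% serum reservoir.
#' @param seed Master seed.  Per-cell RNG streams are derived from it
#'   sequentially, so increasing `n_cells` leaves earlier cells unchanged.
#'
#' @return A `migration_sim_config` list.
#' @export
migration_sim_config <- function(n_cells, n_frames = 49L, frame_interval = 30,
                                 step_speed_mean = 0.8, step_speed_sd = 0.4,
                                 persistence = 0.4, drift_bias = 0,
                                 gradient_axis = c(0, 1), seed = 1L) {
  check_field(is_count(n_cells), "n_cells", "must be a positive integer")
  check_field(is_count(n_frames) && n_frames >= 2, "n_frames",
              "must be an integer >= 2")
  check_field(is_number(frame_interval) && frame_interval > 0,
              "frame_interval", "must be > 0")
  check_field(is_number(step_speed_mean) && step_speed_mean >= 0,
              "step_speed_mean", "must be >= 0")
  check_field(is_number(step_speed_sd) && step_speed_sd >= 0,
              "step_speed_sd", "must be >= 0")
  check_field(is_number(persistence) && persistence >= 0 && persistence < 1,
              "persistence", "must lie in [0, 1)")
  check_field(is_number(drift_bias) && drift_bias >= 0 && drift_bias <= 1,
              "drift_bias", "must lie in [0, 1]")
  gradient_axis <- unit_vector(gradient_axis)
  check_field(is_number(seed), "seed", "must be a finite number")
  structure(
    list(n_cells = as.integer(n_cells), n_frames = as.integer(n_frames),
         frame_interval = frame_interval, step_speed_mean = step_speed_mean,
         step_speed_sd = step_speed_sd, persistence = persistence,
         drift_bias = drift_bias, gradient_axis = gradient_axis,
         seed = as.integer(seed)),
    class = "migration_sim_config"
  )
}

#' Simulate single-cell migration trajectories
#'
#' Generates a [trajectory_set()] from a [migration_sim_config()].  The
#' generator is a pure function of the configuration: identical config and
#' seed give a bitwise-identical set.  Per-cell draw order (after seeding the
#' cell's stream) is: start position (2 uniforms on a 500 um field), initial
#' heading (uniform angle), all step speeds (Gaussian, truncated at zero),
#' then all noise directions (uniform angles); headings are then accumulated
#' deterministically by the resultant rule described in
#' [migration_sim_config()].
#'
#' @param config A [migration_sim_config()].
#' @param condition_label Label for the resulting set; defaults to `"-/+"`
#'   when `drift_bias > 0` and `"+/+"` otherwise.
#' @return A [trajectory_set()] carrying the config's gradient axis.
#' @export
simulate_trajectories <- function(config, condition_label = NULL) {
  if (!inherits(config, "migration_sim_config")) {
    stop("config must be a migration_sim_config", call. = FALSE)
  }
  condition_label <- condition_label %||%
    if (config$drift_bias > 0) "-/+" else "+/+"
  seeds <- derive_stream_seeds(config$seed, config$n_cells)
  times <- (seq_len(config$n_frames) - 1) * config$frame_interval
  g <- config$gradient_axis
  p <- config$persistence
  b <- config$drift_bias
  w_noise <- max(0, 1 - p - b)
  n_steps <- config$n_frames - 1L
  trajs <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) {
    trajs[[i]] <- with_seed(seeds[i], {
      start <- runif(2, 0, 500)
      theta <- runif(1, -pi, pi)
      lens <- pmax(rnorm(n_steps, config$step_speed_mean,
                         config$step_speed_sd), 0) * config$frame_interval
      noise <- runif(n_steps, -pi, pi)
      x <- y <- numeric(config$n_frames)
      x[1] <- start[1]
      y[1] <- start[2]
      for (k in seq_len(n_steps)) {
        vx <- p * cos(theta) + b * g[1] + w_noise * cos(noise[k])
        vy <- p * sin(theta) + b * g[2] + w_noise * sin(noise[k])
        theta <- if (vx == 0 && vy == 0) noise[k] else atan2(vy, vx)
        x[k + 1] <- x[k] + lens[k] * cos(theta)
        y[k + 1] <- y[k] + lens[k] * sin(theta)
      }
      trajectory(sprintf("cell_%03d", i), times, x, y)
    })
  }
  trajectory_set(trajs, condition_label = condition_label, gradient_axis = g)
}

#' Configuration for Brownian bead-track simulation
#'
#' Ground truth for spontaneous nanoscale bead displacements of
#' cytoskeleton-anchored microbeads, emulating acquisition at 12 frames/s for
#' about 300 s with about 100 beads per field of view.  For
#' `anomalous_exponent = 1` increments are independent Gaussians and the
#' ensemble mean squared displacement at lag `t` is `4 * D * t` (nm^2); for
#' other exponents the track is fractional Brownian motion with
#' `MSD(t) = 4 * D * t^alpha`.
#'
#' @param n_beads Number of beads (default 100).
#' @param duration Recording length in seconds (default 300).
#' @param frame_rate Frames per second (default 12).
#' @param diffusion_coefficient Apparent diffusivity `D` in nm^2/s
#'   (must be `>= 0`).
#' @param anomalous_exponent MSD power-law exponent `alpha` (default 1,
#'   ordinary diffusion).  Values `!= 1` use an exact fractional-Gaussian
#'   increment construction whose cost grows quadratically in the number of
#'   frames.
#' @param seed Master seed; per-bead streams derived as in
#'   [migration_sim_config()].
#' @return A `bead_sim_config` list.
#' @export
bead_sim_config <- function(n_beads = 100L, duration = 300, frame_rate = 12,
                            diffusion_coefficient = 2500,
                            anomalous_exponent = 1, seed = 1L) {
  check_field(is_count(n_beads), "n_beads", "must be a positive integer")
  check_field(is_number(duration) && duration > 0, "duration", "must be > 0")
  check_field(is_number(frame_rate) && frame_rate > 0, "frame_rate",
              "must be > 0")
  check_field(duration * frame_rate >= 2, "duration",
              "must give at least 2 samples at the given frame_rate")
  check_field(is_number(diffusion_coefficient) && diffusion_coefficient >= 0,
              "diffusion_coefficient", "must be >= 0")
  check_field(is_number(anomalous_exponent) && anomalous_exponent > 0 &&
                anomalous_exponent <= 2, "anomalous_exponent",
              "must lie in (0, 2]")
  check_field(is_number(seed), "seed", "must be a finite number")
  structure(
    list(n_beads = as.integer(n_beads), duration = duration,
         frame_rate = frame_rate,
         diffusion_coefficient = diffusion_coefficient,
         anomalous_exponent = anomalous_exponent, seed = as.integer(seed)),
    class = "bead_sim_config"
  )
}

# Cholesky factor of the fractional-Gaussian-noise increment covariance on a
# unit grid, scaled so Var(x(t)) = 2 D t^alpha per coordinate.
fgn_chol <- function(n_steps, dt, D, alpha) {
  k <- 0:(n_steps - 1)
  gamma <- D * dt^alpha *
    (abs(k + 1)^alpha - 2 * abs(k)^alpha + abs(k - 1)^alpha)
  gamma[1] <- 2 * D * dt^alpha
  idx <- abs(outer(seq_len(n_steps), seq_len(n_steps), "-")) + 1L
  chol(matrix(gamma[idx], n_steps, n_steps))
}

#' Simulate cytoskeleton-anchored bead tracks
#'
#' @param config A [bead_sim_config()].
#' @return A `bead_track_set`: list with `time` (seconds), position matrices
#'   `x` and `y` (nm, frames by beads, each bead starting at the origin),
#'   `frame_rate`, and the generating config.
#' @export
simulate_bead_tracks <- function(config) {
  if (!inherits(config, "bead_sim_config")) {
    stop("config must be a bead_sim_config", call. = FALSE)
  }
  dt <- 1 / config$frame_rate
  n_frames <- floor(config$duration * config$frame_rate) + 1L
  n_steps <- n_frames - 1L
  D <- config$diffusion_coefficient
  alpha <- config$anomalous_exponent
  seeds <- derive_stream_seeds(config$seed, config$n_beads)
  x <- matrix(0, n_frames, config$n_beads)
  y <- matrix(0, n_frames, config$n_beads)
  L <- if (alpha != 1 && D > 0) fgn_chol(n_steps, dt, D, alpha) else NULL
  sd1 <- sqrt(2 * D * dt)
  for (j in seq_len(config$n_beads)) {
    inc <- with_seed(seeds[j], {
      if (D == 0) {
        matrix(0, n_steps, 2)
      } else if (alpha == 1) {
        cbind(rnorm(n_steps, 0, sd1), rnorm(n_steps, 0, sd1))
      } else {
        z <- matrix(rnorm(2 * n_steps), n_steps, 2)
        crossprod(L, z)
      }
    })
    x[-1, j] <- cumsum(inc[, 1])
    y[-1, j] <- cumsum(inc[, 2])
  }
  structure(
    list(time = (seq_len(n_frames) - 1) * dt, x = x, y = y,
         frame_rate = config$frame_rate, config = config),
    class = "bead_track_set"
  )
}

#' @export
print.bead_track_set <- function(x, ...) {
  cat(sprintf("<bead_track_set> %d beads x %d frames (%.1f s at %g fps)\n",
              ncol(x$x), nrow(x$x), max(x$time), x$frame_rate))
  invisible(x)
}

#' Configuration for synthetic AFM force-indentation curves
#'
#' Ground truth for Hertz-model force curves of a conical tip:
#' `F = 2 E tan(alpha) / (pi (1 - nu^2)) * delta^2` plus additive Gaussian
#' force noise, with indentation spanning `[0, max_indentation]`.
#'
#' @param youngs_modulus_true True Young's modulus in Pa.
#' @param tip_half_angle Tip opening half-angle in degrees (default 35).
#' @param poisson_ratio Poisson ratio in (0, 1), default 0.5 (incompressible
#'   soft material).
#' @param max_indentation Maximum indentation depth in metres.
#' @param n_points Number of samples along the curve.
#' @param force_noise_sd Additive force noise SD in Newtons.
#' @param seed Seed for the noise realization.
#' @return A `hertz_sim_config` list.
#' @export
hertz_sim_config <- function(youngs_modulus_true = 1000, tip_half_angle = 35,
                             poisson_ratio = 0.5, max_indentation = 1e-6,
                             n_points = 200L, force_noise_sd = 0,
                             seed = 1L) {
  check_field(is_number(youngs_modulus_true) && youngs_modulus_true >= 0,
              "youngs_modulus_true", "must be >= 0")
  check_field(is_number(tip_half_angle) && tip_half_angle > 0 &&
                tip_half_angle < 90, "tip_half_angle",
              "must lie strictly between 0 and 90 degrees")
  check_field(is_number(poisson_ratio) && poisson_ratio > 0 &&
                poisson_ratio < 1, "poisson_ratio",
              "must lie strictly between 0 and 1")
  check_field(is_number(max_indentation) && max_indentation > 0,
              "max_indentation", "must be > 0")
  check_field(is_count(n_points) && n_points >= 3, "n_points",
              "must be an integer >= 3")
  check_field(is_number(force_noise_sd) && force_noise_sd >= 0,
              "force_noise_sd", "must be >= 0")
  check_field(is_number(seed), "seed", "must be a finite number")
  structure(
    list(youngs_modulus_true = youngs_modulus_true,
         tip_half_angle = tip_half_angle, poisson_ratio = poisson_ratio,
         max_indentation = max_indentation, n_points = as.integer(n_points),
         force_noise_sd = force_noise_sd, seed = as.integer(seed)),
    class = "hertz_sim_config"
  )
}

#' Simulate an AFM force-indentation curve
#'
#' @param config A [hertz_sim_config()].
#' @return A [force_curve()] with the config attached as attribute
#'   `sim_config`.
#' @export
simulate_force_curve <- function(config) {
  if (!inherits(config, "hertz_sim_config")) {
    stop("config must be a hertz_sim_config", call. = FALSE)
  }
  delta <- seq(0, config$max_indentation, length.out = config$n_points)
  pref <- hertz_prefactor(config$tip_half_angle, config$poisson_ratio)
  f <- pref * config$youngs_modulus_true * delta^2
  noise <- with_seed(config$seed,
                     rnorm(config$n_points, 0, config$force_noise_sd))
  fc <- force_curve(indentation = delta, force = f + noise,
                    tip_half_angle = config$tip_half_angle,
                    poisson_ratio = config$poisson_ratio)
  attr(fc, "sim_config") <- config
  fc
}

#' Simulate a qPCR Ct table with known fold change
#'
#' Generates cycle-threshold values for a target and a housekeeping gene in
#' treated and control conditions such that the expected delta-delta-Ct is
#' `-log2(fold_change_true)`, i.e. the noiseless fold change recovered by
#' [delta_delta_ct()] equals `fold_change_true` exactly.  Gaussian cycle
#' noise of SD `ct_noise_sd` is added independently to each of the four Ct
#' values of each replicate (so the recovered fold is unbiased on the log2
#' scale).
#'
#' @param fold_change_true True expression fold change (> 0).
#' @param n_replicates Number of replicates.
#' @param ct_noise_sd Cycle noise SD (cycles).
#' @param seed Seed.
#' @param ct_target_control,ct_housekeeping Baseline cycle thresholds used
#'   for the control target and the housekeeping gene.
#' @return A `ct_table` data frame with columns `ct_target_treated`,
#'   `ct_housekeeping_treated`, `ct_target_control`,
#'   `ct_housekeeping_control` and attribute `fold_change_true`.
#' @export
simulate_ct_table <- function(fold_change_true, n_replicates = 3L,
                              ct_noise_sd = 0, seed = 1L,
                              ct_target_control = 24,
                              ct_housekeeping = 18) {
  check_field(is_number(fold_change_true) && fold_change_true > 0,
              "fold_change_true", "must be > 0")
  check_field(is_count(n_replicates), "n_replicates",
              "must be a positive integer")
  check_field(is_number(ct_noise_sd) && ct_noise_sd >= 0, "ct_noise_sd",
              "must be >= 0")
  ct_target_treated <- ct_target_control - log2(fold_change_true)
  noise <- with_seed(seed,
                     matrix(rnorm(4L * n_replicates, 0, ct_noise_sd),
                            n_replicates, 4L))
  out <- data.frame(
    ct_target_treated = ct_target_treated + noise[, 1],
    ct_housekeeping_treated = ct_housekeeping + noise[, 2],
    ct_target_control = ct_target_control + noise[, 3],
    ct_housekeeping_control = ct_housekeeping + noise[, 4]
  )
  class(out) <- c("ct_table", "data.frame")
  attr(out, "fold_change_true") <- fold_change_true
  out
}
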