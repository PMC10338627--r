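# Independent brute-force oracles used to cross-check the package's
# estimators.  These deliberately use plain scalar loops / closed forms and
# never call the code paths they verify.

oracle_path_length <- function(x, y) {
  total <- 0
  for (i in seq_along(x)[-1]) {
    total <- total + sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2)
  }
  total
}

# Time-and-ensemble MSD by explicit triple loop over beads, start times, lags.
oracle_msd <- function(xmat, ymat, k) {
  n_frames <- nrow(xmat)
  acc <- 0
  n <- 0
  for (b in seq_len(ncol(xmat))) {
    for (t in seq_len(n_frames - k)) {
      acc <- acc + (xmat[t + k, b] - xmat[t, b])^2 +
        (ymat[t + k, b] - ymat[t, b])^2
      n <- n + 1
    }
  }
  acc / n
}

# Closed-form OLS via the normal equations.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Independent re-implementation of the documented biased persistent
# random-walk update rule for one cell, from its per-cell stream seed.
oracle_walk_cell <- function(cell_seed, n_frames, frame_interval,
                             speed_mean, speed_sd, persistence, drift_bias,
                             g) {
  set.seed(cell_seed)
  start <- runif(2, 0, 500)
  theta <- runif(1, -pi, pi)
  n_steps <- n_frames - 1
  lens <- pmax(rnorm(n_steps, speed_mean, speed_sd), 0) * frame_interval
  noise <- runif(n_steps, -pi, pi)
  w_noise <- max(0, 1 - persistence - drift_bias)
  x <- c(start[1], numeric(n_steps))
  y <- c(start[2], numeric(n_steps))
  for (k in seq_len(n_steps)) {
    vx <- persistence * cos(theta) + drift_bias * g[1] +
      w_noise * cos(noise[k])
    vy <- persistence * sin(theta) + drift_bias * g[2] +
      w_noise * sin(noise[k])
    theta <- if (vx == 0 && vy == 0) noise[k] else atan2(vy, vx)
    x[k + 1] <- x[k] + lens[k] * cos(theta)
    y[k + 1] <- y[k] + lens[k] * sin(theta)
  }
  cbind(x = x, y = y)
}

# The per-cell stream seeds the generators derive from a master seed.
oracle_stream_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(master)
  s <- sample.int(2147483646L, n, replace = TRUE)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

# Exact two-sided Mann-Whitney p by enumerating every split of the pooled
# sample, applying the same two-sided doubling rule as the exact test.
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_of <- function(idx) {
    x <- pooled[idx]
    y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  splits <- utils::combn(length(pooled), n1)
  us <- apply(splits, 2, u_of)
  u_obs <- u_of(seq_len(n1))
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Small random trajectory for property checks.
random_trajectory <- function(id, n = 10, scale = 5) {
  trajectory(id, time = seq(0, by = 30, length.out = n),
             x = cumsum(rnorm(n, 0, scale)), y = cumsum(rnorm(n, 0, scale)))
}

simulate_three_arm_reports <- function(bias_gradient, n_cells, seed,
                                       n_perm = 500L) {
  labs <- c("+/+", "-/-", "-/+")
  bias <- c(0, 0, bias_gradient)
  reports <- vector("list", 3L)
  for (i in 1:3) {
    cfg <- migration_sim_config(n_cells = n_cells, drift_bias = bias[i],
                                seed = seed + i * 101L)
    set <- simulate_trajectories(cfg, condition_label = labs[i])
    reports[[i]] <- chemotaxis_report(set, n_perm = n_perm,
                                      seed = seed + i * 757L)
  }
  reports
}
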