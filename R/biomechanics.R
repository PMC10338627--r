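# Hertz prefactor for a conical tip: F = [2 tan(alpha) / (pi (1 - nu^2))] E d^2.
# Half-angle stored in degrees as instruments print it; converted here.
hertz_prefactor <- function(tip_half_angle, poisson_ratio) {
  check_field(is_number(tip_half_angle) && tip_half_angle > 0 &&
                tip_half_angle < 90, "tip_half_angle",
              "must lie strictly between 0 and 90 degrees")
  if (!is_number(poisson_ratio) || poisson_ratio >= 1 || poisson_ratio <= -1) {
    stop("degenerate parameter: poisson_ratio must satisfy |nu| < 1",
         call. = FALSE)
  }
  2 * tan(tip_half_angle * pi / 180) / (pi * (1 - poisson_ratio^2))
}

#' AFM force-indentation curve
#'
#' Container for one force curve in SI units: indentation depth `delta`
#' (metres, nonnegative, ascending) against cantilever force (Newtons),
#' plus the tip geometry needed by the Hertz model.
#'
#' @param indentation Nonnegative, nondecreasing indentation depths (m).
#' @param force Forces (N), same length.
#' @param tip_half_angle Tip opening half-angle in degrees (default 35).
#' @param poisson_ratio Poisson ratio (default 0.5).
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(indentation, force, tip_half_angle = 35,
                        poisson_ratio = 0.5) {
  stopifnot(is.numeric(indentation), is.numeric(force))
  if (length(indentation) != length(force)) {
    stop("indentation and force must have equal length", call. = FALSE)
  }
  if (anyNA(indentation) || anyNA(force)) {
    stop("force curve samples must be finite", call. = FALSE)
  }
  if (any(indentation < 0)) {
    stop("indentation must be nonnegative", call. = FALSE)
  }
  if (is.unsorted(indentation)) {
    stop("indentation must be ascending", call. = FALSE)
  }
  hertz_prefactor(tip_half_angle, poisson_ratio)  # validates geometry
  structure(
    list(indentation = as.numeric(indentation), force = as.numeric(force),
         tip_half_angle = tip_half_angle, poisson_ratio = poisson_ratio),
    class = "force_curve"
  )
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf(
    "<force_curve> %d points, depth 0-%.3g m, alpha %g deg, nu %g\n",
    length(x$force), max(x$indentation), x$tip_half_angle, x$poisson_ratio))
  invisible(x)
}

#' Fit the Hertz model to a force-indentation curve
#'
#' Estimates Young's modulus `E` from
#' `F = 2 E tan(alpha) / (pi (1 - nu^2)) * delta^2` for a conical tip.
#' Because the model is linear in `E` given `delta^2`, the least-squares
#' optimum is closed form (no iterative optimisation), and a negative
#' estimate -- possible only under extreme noise -- is clamped to zero with
#' a warning.
#'
#' @param curve A [force_curve()].
#' @param max_indentation Optional cap: only samples with
#'   `delta <= max_indentation` enter the fit (mirrors restricting the fit
#'   to the instrument's force-setpoint region).
#' @return An object of class `hertz_fit`: `youngs_modulus` (Pa),
#'   `fit_residual` (RMS force residual, N), `n`, geometry, and fitted
#'   values.  Methods: `print`, `coef`, `predict`, `plot`.
#' @examples
#' cfg <- hertz_sim_config(youngs_modulus_true = 1200)
#' fit <- fit_hertz(simulate_force_curve(cfg))
#' coef(fit)
#' @export
fit_hertz <- function(curve, max_indentation = NULL) {
  stopifnot(inherits(curve, "force_curve"))
  d <- curve$indentation
  f <- curve$force
  if (!is.null(max_indentation)) {
    keep <- d <= max_indentation
    d <- d[keep]
    f <- f[keep]
  }
  pos <- d > 0
  if (sum(pos) < 3L) {
    stop("degenerate curve: need >= 3 points with indentation > 0",
         call. = FALSE)
  }
  pref <- hertz_prefactor(curve$tip_half_angle, curve$poisson_ratio)
  d2 <- d^2
  # LS through the origin in the regressor delta^2
  k_hat <- sum(f * d2) / sum(d2^2)
  e_hat <- k_hat / pref
  if (e_hat < 0) {
    warning("fitted Young's modulus was negative; clamped to 0",
            call. = FALSE)
    e_hat <- 0
  }
  fitted <- pref * e_hat * d2
  structure(
    list(youngs_modulus = e_hat,
         fit_residual = sqrt(mean((f - fitted)^2)),
         n = length(d), tip_half_angle = curve$tip_half_angle,
         poisson_ratio = curve$poisson_ratio,
         indentation = d, force = f, fitted = fitted),
    class = "hertz_fit"
  )
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf(
    "Hertz fit: E = %.6g Pa (RMS residual %.3g N, n = %d, alpha %g deg, nu %g)\n",
    x$youngs_modulus, x$fit_residual, x$n, x$tip_half_angle,
    x$poisson_ratio))
  invisible(x)
}

#' @export
coef.hertz_fit <- function(object, ...) {
  c(youngs_modulus = object$youngs_modulus)
}

#' @export
#' @param object A `hertz_fit`.
#' @param newdata Optional numeric vector of indentation depths (m).
#' @param ... Unused.
#' @rdname fit_hertz
predict.hertz_fit <- function(object, newdata = NULL, ...) {
  d <- newdata %||% object$indentation
  hertz_prefactor(object$tip_half_angle, object$poisson_ratio) *
    object$youngs_modulus * d^2
}

#' @export
plot.hertz_fit <- function(x, ...) {
  plot(x$indentation * 1e9, x$force * 1e12, xlab = "indentation (nm)",
       ylab = "force (pN)", main = "Hertz fit", col = "grey40", ...)
  lines(x$indentation * 1e9, x$fitted * 1e12, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Closed-form single-point Hertz inversion
#'
#' Inverts the conical-tip Hertz relation at one (indentation, force) pair:
#' `E = pi * F * (1 - nu^2) / (2 * tan(alpha) * delta^2)`.
#'
#' @param indentation Indentation depth (m), > 0.
#' @param force Force (N).
#' @param tip_half_angle Tip half-angle (degrees).
#' @param poisson_ratio Poisson ratio.
#' @return Young's modulus in Pa.
#' @export
hertz_point_modulus <- function(indentation, force, tip_half_angle = 35,
                                poisson_ratio = 0.5) {
  stopifnot(is_number(indentation), indentation > 0, is_number(force))
  force / (hertz_prefactor(tip_half_angle, poisson_ratio) * indentation^2)
}

#' Estimate the tip-sample contact point of a raw approach curve
#'
#' AFM approach segments include a pre-contact baseline; the true
#' indentation is measured from the unknown contact point.  The offset is
#' chosen by piecewise least squares: a flat baseline before the candidate
#' contact and a Hertz parabola (in the recomputed indentation) after it,
#' scanned over all candidate samples and refined continuously around the
#' best one.  If the parabolic segment does not improve on an all-flat fit
#' by a clear margin the curve is flagged as having no detectable contact.
#'
#' @param distance Monotone nondecreasing piezo-extension/indentation
#'   coordinate (m) of the approach segment.
#' @param force Measured force (N), same length.
#' @param tip_half_angle,poisson_ratio Tip geometry for the corrected curve.
#' @param min_f_ratio Minimum F-ratio of the piecewise fit over the flat fit
#'   for contact to be declared (default 20).
#' @return An object of class `contact_fit`: `offset` (m), logical
#'   `contact_found`, `baseline` (N), and when contact was found a corrected
#'   [force_curve()] in `curve` (post-contact samples, indentation measured
#'   from the estimated contact).
#' @export
estimate_contact_point <- function(distance, force, tip_half_angle = 35,
                                   poisson_ratio = 0.5, min_f_ratio = 20) {
  stopifnot(is.numeric(distance), is.numeric(force),
            length(distance) == length(force))
  n <- length(distance)
  if (n < 8L) stop("insufficient data: need >= 8 samples", call. = FALSE)
  if (is.unsorted(distance)) {
    stop("approach segment must be monotone in distance", call. = FALSE)
  }
  sse_at <- function(d0) {
    pre <- distance <= d0
    if (sum(pre) < 2L || sum(!pre) < 3L) return(Inf)
    b <- mean(force[pre])
    dd <- (distance[!pre] - d0)^2
    k <- sum((force[!pre] - b) * dd) / sum(dd^2)
    k <- max(k, 0)
    sum((force[pre] - b)^2) + sum((force[!pre] - b - k * dd)^2)
  }
  cand <- distance[seq(2L, n - 3L)]
  sse <- vapply(cand, sse_at, numeric(1))
  best <- which.min(sse)
  # continuous refinement between neighbouring candidates
  lo <- cand[max(1L, best - 1L)]
  hi <- cand[min(length(cand), best + 1L)]
  opt <- if (hi > lo) optimize(sse_at, c(lo, hi)) else
    list(minimum = cand[best], objective = sse[best])
  d0 <- if (opt$objective <= sse[best]) opt$minimum else cand[best]
  sse_best <- min(opt$objective, sse[best])
  sse_flat <- sum((force - mean(force))^2)
  # two extra parameters (offset, Hertz coefficient) vs the flat model
  f_ratio <- ((sse_flat - sse_best) / 2) / (sse_best / max(n - 3L, 1L))
  pre <- distance <= d0
  baseline <- mean(force[pre])
  dd <- (distance[!pre] - d0)^2
  k <- max(sum((force[!pre] - baseline) * dd) / sum(dd^2), 0)
  contact <- is.finite(f_ratio) && f_ratio >= min_f_ratio && k > 0
  out <- list(offset = d0, contact_found = contact, baseline = baseline,
              f_ratio = f_ratio, curve = NULL)
  if (contact) {
    out$curve <- force_curve(indentation = distance[!pre] - d0,
                             force = force[!pre] - baseline,
                             tip_half_angle = tip_half_angle,
                             poisson_ratio = poisson_ratio)
  }
  structure(out, class = "contact_fit")
}

#' @export
print.contact_fit <- function(x, ...) {
  if (x$contact_found) {
    cat(sprintf("Contact point at %.4g m (F-ratio %.3g)\n", x$offset,
                x$f_ratio))
  } else {
    cat(sprintf("No detectable contact (F-ratio %.3g); curve excluded\n",
                x$f_ratio))
  }
  invisible(x)
}

#' Mean squared displacement of bead tracks
#'
#' Time-and-ensemble averaged MSD: for each lag `tau` (a multiple of the
#' frame interval up to `max_lag`), the average of
#' `|r(t + tau) - r(t)|^2` over all overlapping start times of all beads.
#' The lag-zero point is included as 0 by convention.
#'
#' @param tracks A `bead_track_set` from [simulate_bead_tracks()], or any
#'   list with `time` and position matrices `x`, `y` (frames by beads, nm).
#' @param max_lag Largest lag in seconds; must be smaller than the track
#'   duration.
#' @return An object of class `msd_curve`: data frame with `lag` (s), `msd`
#'   (nm^2), `n_pairs`.
#' @export
compute_msd <- function(tracks, max_lag) {
  stopifnot(is.list(tracks), !is.null(tracks$time), is.matrix(tracks$x),
            is.matrix(tracks$y))
  tt <- tracks$time
  n_frames <- length(tt)
  if (n_frames < 2L) {
    stop("insufficient data: need >= 2 frames", call. = FALSE)
  }
  dt <- tt[2] - tt[1]
  duration <- tt[n_frames] - tt[1]
  if (!is_number(max_lag) || max_lag <= 0 || max_lag >= duration) {
    stop("bounds error: max_lag must lie in (0, track duration)",
         call. = FALSE)
  }
  k_max <- floor(max_lag / dt + 1e-9)
  msd <- numeric(k_max)
  n_pairs <- integer(k_max)
  for (k in seq_len(k_max)) {
    dx <- tracks$x[(k + 1):n_frames, , drop = FALSE] -
      tracks$x[1:(n_frames - k), , drop = FALSE]
    dy <- tracks$y[(k + 1):n_frames, , drop = FALSE] -
      tracks$y[1:(n_frames - k), , drop = FALSE]
    msd[k] <- mean(dx^2 + dy^2)
    n_pairs[k] <- length(dx)
  }
  out <- data.frame(lag = c(0, seq_len(k_max) * dt), msd = c(0, msd),
                    n_pairs = c(0L, n_pairs))
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' @export
plot.msd_curve <- function(x, log = "", ...) {
  keep <- x$lag > 0
  plot(x$lag[keep], x$msd[keep], xlab = "lag (s)", ylab = "MSD (nm^2)",
       log = log, type = "b", pch = 16, col = "grey30",
       main = "Mean squared displacement", ...)
  invisible(x)
}

#' Estimate a diffusion coefficient from an MSD curve
#'
#' Ordinary least-squares fit of `MSD(tau) = 4 D tau (+ intercept)`; the
#' slope over 4 is the apparent 2D diffusion coefficient.  For anomalous
#' motion, the log-log slope estimates the MSD power-law exponent.
#'
#' @param msd An [compute_msd()] result.
#' @return List with `D` (nm^2/s), `intercept`, `r_squared`, and
#'   `loglog_slope` (power-law exponent from lags > 0).
#' @export
fit_diffusion <- function(msd) {
  stopifnot(inherits(msd, "msd_curve"))
  fit <- lm(msd ~ lag, data = msd)
  pos <- msd$lag > 0 & msd$msd > 0
  ll <- if (sum(pos) >= 2L) {
    unname(coef(lm(log(msd$msd[pos]) ~ log(msd$lag[pos])))[2])
  } else {
    NA_real_
  }
  list(D = unname(coef(fit)[2]) / 4, intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared, loglog_slope = ll)
}

#' Magnetic twisting cytometry record
#'
#' Specific torque (Pa) and lateral bead displacement (nm) sampled on a
#' common time grid while a sinusoidal twisting field drives the bead at a
#' known frequency.
#'
#' @param time Sample times (s).
#' @param specific_torque Specific torque (Pa), same length as `time`.
#' @param bead_displacement Lateral bead displacement (nm), same length.
#' @param driving_frequency Twisting frequency (Hz).
#' @return An object of class `twisting_record`.
#' @export
twisting_record <- function(time, specific_torque, bead_displacement,
                            driving_frequency) {
  stopifnot(is.numeric(time), is.numeric(specific_torque),
            is.numeric(bead_displacement))
  if (length(time) != length(specific_torque) ||
      length(time) != length(bead_displacement)) {
    stop("torque and displacement must share the time grid", call. = FALSE)
  }
  check_field(is_number(driving_frequency) && driving_frequency > 0,
              "driving_frequency", "must be > 0")
  structure(
    list(time = as.numeric(time), specific_torque = as.numeric(specific_torque),
         bead_displacement = as.numeric(bead_displacement),
         driving_frequency = driving_frequency),
    class = "twisting_record"
  )
}

#' MTC cell stiffness from a twisting record
#'
#' Extracts the amplitude of the specific torque and of the bead
#' displacement at the driving frequency by least-squares sinusoid fitting
#' (regression on sine and cosine at that frequency plus an offset), and
#' reports their ratio as the cell stiffness in Pa/nm.  The estimate is
#' independent of any phase lag between torque and displacement.
#'
#' @param record A [twisting_record()] spanning at least two full driving
#'   periods.
#' @param noise_floor Displacement amplitudes at or below this level (nm)
#'   are treated as unmeasurable (default 0).
#' @return List with `stiffness` (Pa/nm), `torque_amplitude` (Pa),
#'   `displacement_amplitude` (nm), `phase_lag` (radians).
#' @export
mtc_stiffness <- function(record, noise_floor = 0) {
  stopifnot(inherits(record, "twisting_record"))
  span <- max(record$time) - min(record$time)
  if (span * record$driving_frequency < 2) {
    stop("insufficient data: need >= 2 full periods of the driving frequency",
         call. = FALSE)
  }
  w <- 2 * pi * record$driving_frequency
  s <- sin(w * record$time)
  c_ <- cos(w * record$time)
  amp_phase <- function(y) {
    fit <- lm(y ~ s + c_)
    a <- coef(fit)[["s"]]
    b <- coef(fit)[["c_"]]
    c(amplitude = sqrt(a^2 + b^2), phase = atan2(b, a))
  }
  tq <- amp_phase(record$specific_torque)
  dp <- amp_phase(record$bead_displacement)
  if (dp[["amplitude"]] <= noise_floor || dp[["amplitude"]] == 0) {
    stop("unmeasurable stiffness: displacement amplitude at or below the ",
         "noise floor", call. = FALSE)
  }
  list(stiffness = tq[["amplitude"]] / dp[["amplitude"]],
       torque_amplitude = tq[["amplitude"]],
       displacement_amplitude = dp[["amplitude"]],
       phase_lag = tq[["phase"]] - dp[["phase"]])
}
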