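#' Accumulated distance of a trajectory
#'
#' Total path length: the sum of the Euclidean lengths of consecutive
#' segments.  This is the "total distance traveled" metric of single-cell
#' motility analysis; it counts in-place wiggling as well as net movement.
#'
#' @param traj A [trajectory()] with at least two samples.
#' @return Accumulated distance in micrometres (nonnegative scalar).
#' @seealso [euclidean_distance()], [directness()]
#' @export
accumulated_distance <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$time) < 2L) {
    stop("insufficient data: accumulated distance needs >= 2 samples",
         call. = FALSE)
  }
  sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
}

#' Euclidean (net) distance of a trajectory
#'
#' Straight-line length from the first to the last sample: the net distance
#' a cell has displaced, regardless of the path taken.
#'
#' @inheritParams accumulated_distance
#' @return Euclidean distance in micrometres; always `<=`
#'   [accumulated_distance()].
#' @export
euclidean_distance <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  n <- length(traj$time)
  if (n < 2L) {
    stop("insufficient data: Euclidean distance needs >= 2 samples",
         call. = FALSE)
  }
  sqrt((traj$x[n] - traj$x[1])^2 + (traj$y[n] - traj$y[1])^2)
}

#' Directness of a trajectory
#'
#' Ratio of Euclidean over accumulated distance.  A value of 1 means
#' perfectly straight movement; values near 0 mean movement mostly in place.
#' For a cell that did not move at all the ratio is 0/0; it is reported as
#' missing (`NA`), never as 0 or 1, and such cells are dropped from cohort
#' summaries.
#'
#' @inheritParams accumulated_distance
#' @return Directness in `[0, 1]`, or `NA_real_` when the accumulated
#'   distance is zero.
#' @export
directness <- function(traj) {
  acc <- accumulated_distance(traj)
  if (acc == 0) return(NA_real_)
  euclidean_distance(traj) / acc
}

#' Per-cell motility metrics table
#'
#' One row per cell: sample count, accumulated and Euclidean distance,
#' directness, and area when recorded.  Cohort summaries in this package are
#' always per-cell (one number per cell), matching dot-plot style reporting,
#' never per-step pooling.
#'
#' @param set A [trajectory_set()].
#' @return A data frame with columns `cell_id`, `n_samples`,
#'   `accumulated_um`, `euclidean_um`, `directness`, `area_um2`.
#' @export
cell_metrics <- function(set) {
  stopifnot(inherits(set, "trajectory_set"))
  rows <- lapply(set$trajectories, function(t) {
    data.frame(cell_id = t$cell_id, n_samples = length(t$time),
               accumulated_um = accumulated_distance(t),
               euclidean_um = euclidean_distance(t),
               directness = directness(t), area_um2 = t$area,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE))) %||%
    data.frame(cell_id = character(), n_samples = integer(),
               accumulated_um = numeric(), euclidean_um = numeric(),
               directness = numeric(), area_um2 = numeric())
}

#' Translate every trajectory to the origin (spider coordinates)
#'
#' Subtracts each trajectory's first sample from all of its samples so all
#' cells start at (0,0).  Inter-sample displacement vectors -- and therefore
#' all distance metrics -- are unchanged.
#'
#' @param set A [trajectory_set()]; may be empty.
#' @return A `trajectory_set` with identical metadata and translated
#'   coordinates.
#' @export
translate_to_origin <- function(set) {
  stopifnot(inherits(set, "trajectory_set"))
  set$trajectories <- lapply(set$trajectories, function(t) {
    t$x <- t$x - t$x[1]
    t$y <- t$y - t$y[1]
    t
  })
  set
}

#' Apply the migration-assay exclusion rule
#'
#' Removes trajectories carrying any exclusion flag (cell division,
#' apoptosis, or leaving the imaging frame), keeping only cleanly tracked
#' cells.  The number of removals is recorded in the `n_excluded` attribute
#' and reported with [message()] so cohort sizes stay auditable.
#'
#' @param set A [trajectory_set()].
#' @return The filtered `trajectory_set`; attribute `n_excluded` holds the
#'   removal count.  Warns if every cell was excluded.
#' @export
apply_exclusions <- function(set) {
  stopifnot(inherits(set, "trajectory_set"))
  keep <- vapply(set$trajectories, function(t) length(t$flags) == 0L,
                 logical(1))
  n_excl <- sum(!keep)
  if (n_excl > 0) {
    message(sprintf("excluded %d of %d cells (division/apoptosis/out of frame)",
                    n_excl, length(keep)))
  }
  set$trajectories <- set$trajectories[keep]
  if (length(set$trajectories) == 0L && n_excl > 0) {
    warning("all cells were excluded; the set is empty", call. = FALSE)
  }
  attr(set, "n_excluded") <- n_excl
  set
}

#' Regress a motility metric on cell area
#'
#' Ordinary least-squares fit of a per-cell motility metric against 2D cell
#' surface area, used to ask whether apparent motility differences are a mere
#' cell-size effect (slope and R-squared near zero say they are not).
#'
#' @param set A [trajectory_set()] whose cells carry areas.
#' @param metric One of `"euclidean"`, `"directness"`, `"accumulated"`.
#' @return An object of class `area_regression`: list with `slope`,
#'   `intercept`, `r_squared`, `n`, `metric`, and the underlying `lm` fit.
#' @export
regress_metric_vs_area <- function(set,
                                   metric = c("euclidean", "directness",
                                              "accumulated")) {
  metric <- match.arg(metric)
  m <- cell_metrics(set)
  y <- switch(metric, euclidean = m$euclidean_um,
              directness = m$directness, accumulated = m$accumulated_um)
  ok <- !is.na(m$area_um2) & !is.na(y)
  if (sum(ok) < 3L) {
    stop("insufficient data: need >= 3 cells with area and metric",
         call. = FALSE)
  }
  area <- m$area_um2[ok]
  y <- y[ok]
  if (var(area) == 0) {
    stop("degenerate regressor: all cell areas are identical", call. = FALSE)
  }
  fit <- lm(y ~ area)
  # R^2 computed directly (avoids summary.lm's perfect-fit warning)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r2, n = sum(ok), metric = metric,
         fit = fit),
    class = "area_regression"
  )
}

#' @export
print.area_regression <- function(x, ...) {
  cat(sprintf("OLS %s ~ area: slope %.4g, intercept %.4g, R^2 %.4g (n = %d)\n",
              x$metric, x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}
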