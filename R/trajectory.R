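#' Single-cell trajectory
#'
#' A `trajectory` holds the time-ordered 2D positions of one tracked cell,
#' in micrometres against minutes, together with optional cell area and the
#' exclusion flags used by migration assays (cells that divided, underwent
#' apoptosis, or left the imaging frame are excluded from analysis).
#'
#' @param cell_id Identifier, coerced to character.
#' @param time Numeric vector of acquisition times in minutes, strictly
#'   increasing.
#' @param x,y Numeric position coordinates in micrometres (Cartesian, +y up).
#' @param area Optional 2D cell surface area in square micrometres.
#' @param flags Character vector, any subset of
#'   `c("divided", "apoptosed", "left_frame")`.
#'
#' @return An object of class `trajectory`.
#' @examples
#' tr <- trajectory("c1", time = c(0, 30, 60), x = c(0, 3, 3), y = c(0, 0, 4))
#' accumulated_distance(tr)
#' @export
trajectory <- function(cell_id, time, x, y, area = NA_real_,
                       flags = character()) {
  cell_id <- as.character(cell_id)
  stopifnot(length(cell_id) == 1L, is.numeric(time), is.numeric(x),
            is.numeric(y))
  n <- length(time)
  if (length(x) != n || length(y) != n) {
    stop("time, x and y must have equal length", call. = FALSE)
  }
  if (n < 1L) stop("a trajectory needs at least one sample", call. = FALSE)
  if (anyNA(time) || anyNA(x) || anyNA(y)) {
    stop("trajectory samples must be finite", call. = FALSE)
  }
  if (n > 1L && any(diff(time) <= 0)) {
    stop("trajectory times must be strictly increasing", call. = FALSE)
  }
  known <- c("divided", "apoptosed", "left_frame")
  flags <- as.character(flags)
  if (!all(flags %in% known)) {
    stop("unknown exclusion flag; allowed: ", paste(known, collapse = ", "),
         call. = FALSE)
  }
  if (!is.na(area) && (!is_number(area) || area <= 0)) {
    stop("area, when present, must be a positive number", call. = FALSE)
  }
  structure(
    list(cell_id = cell_id, time = as.numeric(time), x = as.numeric(x),
         y = as.numeric(y), area = as.numeric(area), flags = flags),
    class = "trajectory"
  )
}

#' Set of trajectories from one imaging condition
#'
#' Bundles the trajectories of one experimental arm.  Condition labels follow
#' the serum-condition shorthand of gradient migration assays: `"+/+"`
#' (uniform 20% FBS), `"-/-"` (uniform serum-free), `"-/+"` (0-20% FBS
#' gradient).  When a gradient is present, `gradient_axis` is the unit vector
#' pointing from the 0% toward the 20% FBS reservoir.
#'
#' @param trajectories List of [trajectory()] objects with unique cell ids.
#' @param condition_label Single string labelling the arm.
#' @param gradient_axis Unit 2-vector of the chemoattractant gradient, or
#'   `NULL` when no gradient is declared.
#'
#' @return An object of class `trajectory_set`.
#' @export
trajectory_set <- function(trajectories, condition_label = "+/+",
                           gradient_axis = NULL) {
  stopifnot(is.list(trajectories))
  if (!all(vapply(trajectories, inherits, logical(1), "trajectory"))) {
    stop("all elements must be trajectory objects", call. = FALSE)
  }
  ids <- vapply(trajectories, function(t) t$cell_id, character(1))
  if (anyDuplicated(ids)) {
    stop("cell ids must be unique within a trajectory set", call. = FALSE)
  }
  stopifnot(is.character(condition_label), length(condition_label) == 1L)
  if (!is.null(gradient_axis)) gradient_axis <- unit_vector(gradient_axis)
  structure(
    list(trajectories = trajectories, condition_label = condition_label,
         gradient_axis = gradient_axis),
    class = "trajectory_set"
  )
}

#' @export
length.trajectory_set <- function(x) length(x$trajectories)

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory '%s'> %d samples, %.0f-%.0f min%s%s\n",
              x$cell_id, length(x$time), min(x$time), max(x$time),
              if (is.na(x$area)) "" else sprintf(", area %.1f um^2", x$area),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","),
                                          "]") else ""))
  invisible(x)
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d cells, condition '%s'%s\n",
              length(x), x$condition_label,
              if (is.null(x$gradient_axis)) ", no gradient" else
                sprintf(", gradient axis (%.2f, %.2f)",
                        x$gradient_axis[1], x$gradient_axis[2])))
  invisible(x)
}

#' @export
summary.trajectory_set <- function(object, ...) {
  m <- cell_metrics(object)
  cat(sprintf("Trajectory set: %d cells, condition '%s'\n",
              length(object), object$condition_label))
  cat(sprintf("  accumulated distance (um): median %.2f [%.2f, %.2f]\n",
              stats::median(m$accumulated_um),
              min(m$accumulated_um), max(m$accumulated_um)))
  cat(sprintf("  Euclidean distance  (um): median %.2f [%.2f, %.2f]\n",
              stats::median(m$euclidean_um),
              min(m$euclidean_um), max(m$euclidean_um)))
  d <- m$directness[!is.na(m$directness)]
  if (length(d)) {
    cat(sprintf("  directness: median %.3f [%.3f, %.3f]\n",
                stats::median(d), min(d), max(d)))
  }
  invisible(m)
}

#' Long-format table of a trajectory set
#'
#' @param x A `trajectory_set`.
#' @param row.names,optional Unused, for S3 compatibility.
#' @param ... Unused.
#' @return A data frame with columns `track_id`, `time_min`, `x_um`, `y_um`.
#' @export
as.data.frame.trajectory_set <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  rows <- lapply(x$trajectories, function(t) {
    data.frame(track_id = t$cell_id, time_min = t$time,
               x_um = t$x, y_um = t$y, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out %||% data.frame(track_id = character(), time_min = numeric(),
                      x_um = numeric(), y_um = numeric())
}

#' Spider plot of a trajectory set
#'
#' Draws every trajectory translated so its first sample sits at the origin
#' (the standard "spider plot" of migration assays).  Tracks whose endpoint
#' lies up-gradient are drawn in a highlight colour when a gradient axis is
#' declared.
#'
#' @param x A `trajectory_set`.
#' @param main Plot title.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return Invisibly, the translated set.
#' @export
plot.trajectory_set <- function(x, main = NULL, ...) {
  ts <- translate_to_origin(x)
  xs <- unlist(lapply(ts$trajectories, `[[`, "x"))
  ys <- unlist(lapply(ts$trajectories, `[[`, "y"))
  lim <- max(abs(c(xs, ys, 1)))
  plot(NA, xlim = c(-lim, lim), ylim = c(-lim, lim), asp = 1,
       xlab = "x (um)", ylab = "y (um)",
       main = main %||% sprintf("Spider plot (%s)", x$condition_label), ...)
  abline(h = 0, v = 0, col = "grey80")
  g <- x$gradient_axis
  for (t in ts$trajectories) {
    up <- !is.null(g) &&
      (t$x[length(t$x)] * g[1] + t$y[length(t$y)] * g[2]) > 0
    lines(t$x, t$y, col = if (up) "firebrick" else "grey30")
  }
  invisible(ts)
}
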