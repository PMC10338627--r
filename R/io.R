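#' Trajectory-table dialect
#'
#' Tracking tools export trajectory tables with varying column layouts,
#' pixel units, and the image convention that +y points down.  A dialect
#' declares the column mapping and the calibration needed to convert such a
#' table to micrometre/minute Cartesian coordinates (+y up, so "up the
#' gradient" is consistent across sources).
#'
#' @param columns Named list/character mapping the roles `track_id`,
#'   `frame`, `x`, `y` to column names in the file.
#' @param pixel_size Micrometres per pixel (> 0); use 1 if the file is
#'   already in micrometres.
#' @param frame_interval Minutes per frame (> 0); ignored when
#'   `time_unit = "minutes"`.
#' @param time_unit `"frame"` (default) if the time column holds frame
#'   numbers, `"minutes"` if it already holds minutes.
#' @param y_axis_direction `"image_down"` (default; y is negated on import)
#'   or `"cartesian_up"`.
#' @param gradient_axis Optional gradient axis declaration (unit 2-vector in
#'   the Cartesian frame after import).
#' @return A `trajectory_dialect` list.
#' @export
trajectory_dialect <- function(columns = list(track_id = "track_id",
                                              frame = "frame",
                                              x = "x", y = "y"),
                               pixel_size = 1, frame_interval = 30,
                               time_unit = c("frame", "minutes"),
                               y_axis_direction = c("image_down",
                                                    "cartesian_up"),
                               gradient_axis = NULL) {
  time_unit <- match.arg(time_unit)
  y_axis_direction <- match.arg(y_axis_direction)
  need <- c("track_id", "frame", "x", "y")
  columns <- as.list(columns)
  if (!all(need %in% names(columns))) {
    stop("schema error: dialect must map columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  check_field(is_number(pixel_size) && pixel_size > 0, "pixel_size",
              "must be > 0")
  check_field(is_number(frame_interval) && frame_interval > 0,
              "frame_interval", "must be > 0")
  if (!is.null(gradient_axis)) gradient_axis <- unit_vector(gradient_axis)
  structure(
    list(columns = columns, pixel_size = pixel_size,
         frame_interval = frame_interval, time_unit = time_unit,
         y_axis_direction = y_axis_direction, gradient_axis = gradient_axis),
    class = "trajectory_dialect"
  )
}

#' Read a trajectory table
#'
#' Reads a CSV/TSV trajectory export (separator chosen by file extension),
#' applies the dialect's column mapping and calibration (pixels to um,
#' frames to minutes, image-convention y flip), orders each track by frame,
#' and reports malformed rows by line number.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file with a header row.
#' @param dialect A [trajectory_dialect()].
#' @param condition_label Condition label for the resulting set.
#' @return A [trajectory_set()].
#' @export
read_trajectories <- function(path, dialect = trajectory_dialect(),
                              condition_label = "+/+") {
  stopifnot(inherits(dialect, "trajectory_dialect"))
  if (!file.exists(path)) {
    stop("schema error: file not found: ", path, call. = FALSE)
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  cols <- dialect$columns
  missing_cols <- setdiff(unlist(cols), names(raw))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(track_id = as.character(raw[[cols$track_id]]),
                   frame = suppressWarnings(as.numeric(raw[[cols$frame]])),
                   x = suppressWarnings(as.numeric(raw[[cols$x]])),
                   y = suppressWarnings(as.numeric(raw[[cols$y]])),
                   stringsAsFactors = FALSE)
  bad <- !complete.cases(df[c("frame", "x", "y")]) | df$track_id == ""
  if (any(bad)) {
    # +1 for the header line
    warning(sprintf("dropped %d malformed row(s) at line(s): %s", sum(bad),
                    paste(which(bad) + 1L, collapse = ", ")), call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0L) {
    stop("data error: no valid rows in ", path, call. = FALSE)
  }
  ysign <- if (dialect$y_axis_direction == "image_down") -1 else 1
  trajs <- lapply(split(df, df$track_id), function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    if (anyDuplicated(tr$frame)) {
      stop("data error: duplicate frames within track ", tr$track_id[1],
           call. = FALSE)
    }
    tmin <- if (dialect$time_unit == "frame") {
      tr$frame * dialect$frame_interval
    } else {
      tr$frame
    }
    trajectory(tr$track_id[1], time = tmin,
               x = tr$x * dialect$pixel_size,
               y = ysign * tr$y * dialect$pixel_size)
  })
  trajectory_set(unname(trajs), condition_label = condition_label,
                 gradient_axis = dialect$gradient_axis)
}

#' Write a trajectory set as CSV
#'
#' Emits the long-format table with units declared in the header
#' (`track_id, time_min, x_um, y_um`), readable back with the identity
#' dialect (`pixel_size = 1`, `time_unit = "minutes"`,
#' `y_axis_direction = "cartesian_up"`).
#'
#' @param set A [trajectory_set()].
#' @param path Output file path (`.csv`).
#' @return Invisibly, `path`.
#' @export
write_trajectories <- function(set, path) {
  stopifnot(inherits(set, "trajectory_set"))
  write.csv(as.data.frame(set), path, row.names = FALSE)
  invisible(path)
}

# Dialect matching write_trajectories() output.
roundtrip_dialect <- function(gradient_axis = NULL) {
  trajectory_dialect(columns = list(track_id = "track_id",
                                    frame = "time_min", x = "x_um",
                                    y = "y_um"),
                     pixel_size = 1, time_unit = "minutes",
                     y_axis_direction = "cartesian_up",
                     gradient_axis = gradient_axis)
}

#' Run the full migration-analysis pipeline
#'
#' Executes, per condition: input loading (or simulation), exclusion
#' filtering, per-cell metrics, spider coordinates; then the chemotaxis
#' analysis (both Rayleigh tests, FMIs, decision rule) across the three
#' arms.  Writes per-cell metric CSVs, spider-coordinate CSVs, a chemotaxis
#' report JSON, and a run log recording seeds, versions, and excluded-cell
#' counts.  All randomness flows from the config seed, so a rerun with the
#' same inputs is byte-identical.
#'
#' @param config A named list, or the path of a YAML/JSON file holding one.
#'   Keys: `output_dir` (required); `seed` (default 1); `alpha` (0.05);
#'   `near_zero_epsilon` (0.1); `n_perm` (10000); `chemotaxis`
#'   (logical, default `TRUE` when three conditions are present);
#'   `gradient_label` (`"-/+"`); `control_labels` (`c("+/+", "-/-")`);
#'   `conditions`: a list whose entries each have `label` plus either
#'   `path` (+ optional dialect keys `pixel_size`, `frame_interval`,
#'   `time_unit`, `y_axis_direction`, `columns`) or `simulate` (fields of
#'   [migration_sim_config()], seed defaulting to the run seed);
#'   `gradient_axis` (2-vector, required for chemotaxis of file inputs).
#' @return Invisibly, a list with the per-condition sets, metric tables,
#'   chemotaxis reports, the verdict (or `NULL`), and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out_dir <- config$output_dir
  if (is.null(out_dir)) {
    stop("configuration error: output_dir is required", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  alpha <- config$alpha %||% 0.05
  eps <- config$near_zero_epsilon %||% 0.1
  n_perm <- as.integer(config$n_perm %||% 10000L)
  conds <- config$conditions
  if (is.null(conds) || !length(conds)) {
    stop("configuration error: no conditions declared", call. = FALSE)
  }
  gradient_axis <- if (!is.null(config$gradient_axis)) {
    unit_vector(unlist(config$gradient_axis))
  } else {
    NULL
  }

  log_lines <- c(sprintf("paccmotion %s", packageVersion("paccmotion")),
                 sprintf("R %s", getRversion()),
                 sprintf("seed %d", seed))
  sets <- list()
  metrics <- list()
  paths <- character()
  for (i in seq_along(conds)) {
    cc <- conds[[i]]
    lab <- cc$label %||% stop("configuration error: condition ", i,
                              " has no label", call. = FALSE)
    set <- if (!is.null(cc$simulate)) {
      sim <- cc$simulate
      sim$seed <- sim$seed %||% (seed + i)
      if (!is.null(sim$gradient_axis)) {
        sim$gradient_axis <- unlist(sim$gradient_axis)
      } else if (!is.null(gradient_axis)) {
        sim$gradient_axis <- gradient_axis
      }
      cfg <- do.call(migration_sim_config, sim)
      simulate_trajectories(cfg, condition_label = lab)
    } else if (!is.null(cc$path)) {
      dial <- trajectory_dialect(
        columns = cc$columns %||% list(track_id = "track_id",
                                       frame = "frame", x = "x", y = "y"),
        pixel_size = cc$pixel_size %||% 1,
        frame_interval = cc$frame_interval %||% 30,
        time_unit = cc$time_unit %||% "frame",
        y_axis_direction = cc$y_axis_direction %||% "image_down",
        gradient_axis = gradient_axis)
      read_trajectories(cc$path, dial, condition_label = lab)
    } else {
      stop("configuration error: condition '", lab,
           "' needs either 'path' or 'simulate'", call. = FALSE)
    }
    if (!is.null(gradient_axis)) set$gradient_axis <- gradient_axis
    n_before <- length(set)
    set <- suppressMessages(apply_exclusions(set))
    log_lines <- c(log_lines,
                   sprintf("condition '%s': %d cells tracked, %d excluded, %d analysed",
                           lab, n_before, attr(set, "n_excluded"),
                           length(set)))
    sets[[lab]] <- set
    m <- cell_metrics(set)
    metrics[[lab]] <- m
    safe <- gsub("[^A-Za-z0-9]+", "_", lab)
    p_m <- file.path(out_dir, sprintf("metrics_%s.csv", safe))
    write.csv(m, p_m, row.names = FALSE)
    p_s <- file.path(out_dir, sprintf("spider_%s.csv", safe))
    write.csv(as.data.frame(translate_to_origin(set)), p_s,
              row.names = FALSE)
    paths <- c(paths, p_m, p_s)
  }

  do_chemo <- config$chemotaxis %||% (length(sets) == 3L)
  verdict <- NULL
  reports <- NULL
  if (isTRUE(do_chemo)) {
    if (any(vapply(sets, function(s) is.null(s$gradient_axis), logical(1)))) {
      stop("configuration error: chemotaxis requested but gradient_axis ",
           "is missing", call. = FALSE)
    }
    reports <- lapply(seq_along(sets), function(i) {
      chemotaxis_report(sets[[i]], n_perm = n_perm, seed = seed + 1000L + i)
    })
    verdict <- classify_chemotaxis(
      reports, alpha = alpha, near_zero_epsilon = eps,
      gradient_label = config$gradient_label %||% "-/+",
      control_labels = unlist(config$control_labels %||% c("+/+", "-/-")))
    rep_json <- list(
      verdict = verdict$verdict,
      criteria = as.list(verdict$criteria),
      alpha = alpha, near_zero_epsilon = eps,
      conditions = lapply(reports, function(r) {
        list(condition_label = r$condition_label, n = r$n,
             rayleigh_p = r$rayleigh_p,
             rayleigh_vector_p = r$rayleigh_vector_p,
             fmi_parallel = r$fmi_parallel,
             fmi_perpendicular = r$fmi_perpendicular)
      }))
    p_j <- file.path(out_dir, "chemotaxis_report.json")
    jsonlite::write_json(rep_json, p_j, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, p_j)
    log_lines <- c(log_lines,
                   sprintf("chemotaxis verdict: %s", verdict$verdict))
  }
  p_log <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, p_log)
  paths <- c(paths, p_log)
  invisible(list(sets = sets, metrics = metrics, reports = reports,
                 verdict = verdict, paths = paths))
}
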