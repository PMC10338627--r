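#' Endpoint displacement vectors of a trajectory set
#'
#' For each cell, the displacement from first to last sample -- the endpoint
#' of its spider-plot track -- with polar decomposition.
#'
#' @param set A [trajectory_set()].
#' @return Data frame with columns `cell_id`, `dx`, `dy` (um), `angle`
#'   (radians in `(-pi, pi]`, `atan2(dy, dx)`), `magnitude` (um).
#' @export
endpoint_vectors <- function(set) {
  stopifnot(inherits(set, "trajectory_set"))
  rows <- lapply(set$trajectories, function(t) {
    n <- length(t$time)
    dx <- t$x[n] - t$x[1]
    dy <- t$y[n] - t$y[1]
    data.frame(cell_id = t$cell_id, dx = dx, dy = dy,
               angle = atan2(dy, dx), magnitude = sqrt(dx^2 + dy^2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE))) %||%
    data.frame(cell_id = character(), dx = numeric(), dy = numeric(),
               angle = numeric(), magnitude = numeric())
}

#' Forward migration indices
#'
#' Per cell, the component of the endpoint displacement parallel
#' (respectively perpendicular) to the gradient axis, divided by that cell's
#' accumulated path length; the cohort index is the arithmetic mean over
#' cells.  Positive parallel FMI means net movement up-gradient, negative
#' means down-gradient.  For every cell the two components satisfy
#' `fmi_parallel^2 + fmi_perpendicular^2 == directness^2`.
#'
#' Cells with zero accumulated distance have undefined indices; they are
#' reported as missing and dropped from the cohort means.
#'
#' @param set A [trajectory_set()] with a declared `gradient_axis`.
#' @return An object of class `fmi`: list with cohort means `fmi_parallel`
#'   and `fmi_perpendicular`, a per-cell data frame `cells` (`cell_id`,
#'   `fmi_parallel`, `fmi_perpendicular`, `directness`), and counts `n_used`,
#'   `n_missing`.
#' @export
forward_migration_indices <- function(set) {
  stopifnot(inherits(set, "trajectory_set"))
  if (is.null(set$gradient_axis)) {
    stop("configuration error: gradient_axis is required for FMI",
         call. = FALSE)
  }
  g <- set$gradient_axis
  perp <- c(-g[2], g[1])
  ep <- endpoint_vectors(set)
  acc <- vapply(set$trajectories, accumulated_distance, numeric(1))
  par_comp <- ifelse(acc > 0, (ep$dx * g[1] + ep$dy * g[2]) / acc, NA_real_)
  perp_comp <- ifelse(acc > 0, (ep$dx * perp[1] + ep$dy * perp[2]) / acc,
                      NA_real_)
  cells <- data.frame(cell_id = ep$cell_id, fmi_parallel = par_comp,
                      fmi_perpendicular = perp_comp,
                      directness = ifelse(acc > 0, ep$magnitude / acc,
                                          NA_real_),
                      stringsAsFactors = FALSE)
  ok <- !is.na(par_comp)
  structure(
    list(fmi_parallel = mean(par_comp[ok]),
         fmi_perpendicular = mean(perp_comp[ok]),
         cells = cells, n_used = sum(ok), n_missing = sum(!ok),
         condition_label = set$condition_label),
    class = "fmi"
  )
}

#' @export
print.fmi <- function(x, ...) {
  cat(sprintf(
    "FMI (%s): parallel %.4f, perpendicular %.4f (n = %d%s)\n",
    x$condition_label, x$fmi_parallel, x$fmi_perpendicular, x$n_used,
    if (x$n_missing) sprintf(", %d missing", x$n_missing) else ""))
  invisible(x)
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether angles are uniformly distributed on the circle against a
#' unimodal concentration.  The statistic is `Z = n * Rbar^2` with `Rbar`
#' the mean resultant length; the p-value uses the standard small-sample
#' corrected exponential approximation
#' `exp(-Z) * (1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288n^2))`,
#' clamped to `[0, 1]`.
#'
#' @param angles Numeric vector of at least 3 finite angles in radians.
#' @return An object of classes `rayleigh_test` and `htest` with `statistic`
#'   (`Z`), `estimate` (mean resultant length), `parameter` (`n`), and
#'   `p.value`.
#' @references Classical circular-statistics treatment of the Rayleigh test
#'   (e.g. Zar, Biostatistical Analysis; Mardia & Jupp, Directional
#'   Statistics).
#' @export
rayleigh_test <- function(angles) {
  angles <- as.numeric(angles)
  if (length(angles) < 3L || anyNA(angles) || any(!is.finite(angles))) {
    stop("insufficient data: need >= 3 finite angles", call. = FALSE)
  }
  n <- length(angles)
  c_bar <- mean(cos(angles))
  s_bar <- mean(sin(angles))
  rbar <- sqrt(c_bar^2 + s_bar^2)
  z <- n * rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  p <- min(max(p, 0), 1)
  structure(
    list(statistic = c(Z = z), parameter = c(n = n), p.value = p,
         estimate = c(mean_resultant_length = rbar),
         method = "Rayleigh test of circular uniformity",
         data.name = deparse(substitute(angles))),
    class = c("rayleigh_test", "htest")
  )
}

# Moore's rank-weighted resultant statistic: magnitudes replaced by ranks,
# resultant of rank-weighted unit vectors, normalized by n^(3/2).
moore_statistic <- function(angles, ranks) {
  n <- length(angles)
  sqrt(sum(ranks * cos(angles))^2 + sum(ranks * sin(angles))^2) / n^1.5
}

#' Rayleigh-type test for vector data (Moore's rank modification)
#'
#' Extends the Rayleigh test to weighted endpoints: each endpoint's
#' magnitude is replaced by its rank (mid-ranks on ties), the resultant of
#' rank-weighted unit vectors is computed, and the statistic is that
#' resultant length normalized by `n^(3/2)`.  The null hypothesis is
#' circular uniformity of the directions; the p-value is obtained by seeded
#' Monte-Carlo simulation of the statistic under that null (the observed
#' ranks paired with independently drawn uniform angles), which matches the
#' tabulated null distribution of the rank-weighted resultant up to
#' simulation error.
#'
#' @param endpoints A data frame with columns `angle` and `magnitude` (as
#'   returned by [endpoint_vectors()]), or a [trajectory_set()].
#' @param n_perm Number of Monte-Carlo null draws (default 10000).
#' @param seed Optional seed for the Monte-Carlo draw; the caller's RNG
#'   state is preserved.
#' @return An object of classes `rayleigh_vector_test` and `htest`; the
#'   `ties` element records whether mid-ranks were used.
#' @export
rayleigh_test_vector <- function(endpoints, n_perm = 10000L, seed = NULL) {
  if (inherits(endpoints, "trajectory_set")) {
    endpoints <- endpoint_vectors(endpoints)
  }
  stopifnot(is.data.frame(endpoints),
            all(c("angle", "magnitude") %in% names(endpoints)))
  a <- endpoints$angle
  m <- endpoints$magnitude
  n <- length(a)
  if (n < 3L || anyNA(a) || anyNA(m)) {
    stop("insufficient data: need >= 3 finite endpoints", call. = FALSE)
  }
  check_field(is_count(n_perm), "n_perm", "must be a positive integer")
  ties <- anyDuplicated(m) > 0L
  r <- rank(m)  # mid-ranks on ties
  obs <- moore_statistic(a, r)
  null_draws <- with_seed(seed, {
    au <- matrix(runif(n * n_perm, -pi, pi), n, n_perm)
    sqrt(crossprod(cos(au), r)^2 + crossprod(sin(au), r)^2) / n^1.5
  })
  p <- (1 + sum(null_draws >= obs)) / (n_perm + 1)
  structure(
    list(statistic = c(R_star = obs), parameter = c(n = n, n_perm = n_perm),
         p.value = p, ties = ties,
         method = paste0("Rayleigh test for vector data ",
                         "(Moore's rank modification, Monte-Carlo p)",
                         if (ties) "; mid-ranks used for tied magnitudes"),
         data.name = "endpoint vectors"),
    class = c("rayleigh_vector_test", "htest")
  )
}

#' Per-condition chemotaxis report
#'
#' Runs both circular tests and the forward migration indices on one
#' condition's trajectory set, producing the inputs of
#' [classify_chemotaxis()].
#'
#' @param set A [trajectory_set()] with a declared gradient axis.
#' @param n_perm Permutations for the vector-data test.
#' @param seed Optional seed for the permutation draw.
#' @return An object of class `chemotaxis_report`: list with
#'   `condition_label`, `rayleigh_p`, `rayleigh_vector_p`, cohort
#'   `fmi_parallel` / `fmi_perpendicular`, per-cell
#'   `fmi_parallel_values` / `fmi_perpendicular_values`, and `n`.
#' @export
chemotaxis_report <- function(set, n_perm = 10000L, seed = NULL) {
  stopifnot(inherits(set, "trajectory_set"))
  ep <- endpoint_vectors(set)
  fmi <- forward_migration_indices(set)
  ray <- rayleigh_test(ep$angle)
  rayv <- rayleigh_test_vector(ep, n_perm = n_perm, seed = seed)
  keep <- !is.na(fmi$cells$fmi_parallel)
  structure(
    list(condition_label = set$condition_label,
         rayleigh_p = ray$p.value, rayleigh_vector_p = rayv$p.value,
         fmi_parallel = fmi$fmi_parallel,
         fmi_perpendicular = fmi$fmi_perpendicular,
         fmi_parallel_values = fmi$cells$fmi_parallel[keep],
         fmi_perpendicular_values = fmi$cells$fmi_perpendicular[keep],
         n = fmi$n_used),
    class = "chemotaxis_report"
  )
}

#' @export
print.chemotaxis_report <- function(x, ...) {
  cat(sprintf("Chemotaxis report, condition '%s' (n = %d cells)\n",
              x$condition_label, x$n))
  cat(sprintf("  Rayleigh p = %.4g; Rayleigh (vector data) p = %.4g\n",
              x$rayleigh_p, x$rayleigh_vector_p))
  cat(sprintf("  FMI parallel = %.4f, perpendicular = %.4f\n",
              x$fmi_parallel, x$fmi_perpendicular))
  invisible(x)
}

#' Three-criterion chemotaxis decision rule
#'
#' Declares a cohort chemotactic only when every part of the standard
#' decision procedure holds across the gradient arm and both uniform-media
#' control arms:
#'
#' * Rayleigh rule: both circular tests significant (`p < alpha`) in the
#'   gradient condition and nonsignificant in both controls;
#' * (i) the parallel FMI of the gradient condition is significantly higher
#'   than the parallel FMI of each control (one-sided Mann-Whitney on
#'   per-cell components);
#' * (ii) the parallel FMI of the gradient condition is significantly higher
#'   than its own perpendicular FMI, which must be close to zero;
#' * (iii) parallel and perpendicular FMIs of both controls are close to
#'   zero.
#'
#' "Close to zero" means `|cohort FMI| <= near_zero_epsilon`.
#'
#' @param reports Named list of three [chemotaxis_report()] objects; names
#'   (or the reports' own condition labels) must cover the gradient label
#'   and both control labels.
#' @param alpha Significance level (default 0.05).
#' @param near_zero_epsilon Closeness-to-zero bound on cohort FMIs
#'   (default 0.1).
#' @param gradient_label,control_labels Condition labels identifying the
#'   arms (defaults `"-/+"` and `c("+/+", "-/-")`).
#' @return An object of class `chemotaxis_verdict`: list with logical
#'   `verdict`, a named logical vector `criteria` tracing every component
#'   check, and the parameters used.
#' @export
classify_chemotaxis <- function(reports, alpha = 0.05,
                                near_zero_epsilon = 0.1,
                                gradient_label = "-/+",
                                control_labels = c("+/+", "-/-")) {
  stopifnot(is.list(reports))
  labs <- vapply(reports, function(r) r$condition_label, character(1))
  pick <- function(lab) {
    i <- match(lab, labs)
    if (is.na(i)) {
      stop(sprintf("configuration error: missing condition '%s'", lab),
           call. = FALSE)
    }
    reports[[i]]
  }
  grad <- pick(gradient_label)
  ctrls <- lapply(control_labels, pick)
  one_sided_higher <- function(x, y) {
    suppressWarnings(wilcox.test(x, y, alternative = "greater")$p.value) <
      alpha
  }
  crit <- c(
    rayleigh_gradient_significant =
      grad$rayleigh_p < alpha && grad$rayleigh_vector_p < alpha,
    rayleigh_controls_nonsignificant =
      all(vapply(ctrls, function(r)
        r$rayleigh_p >= alpha && r$rayleigh_vector_p >= alpha, logical(1))),
    fmi_parallel_above_controls =
      all(vapply(ctrls, function(r)
        one_sided_higher(grad$fmi_parallel_values, r$fmi_parallel_values),
        logical(1))),
    fmi_parallel_above_own_perpendicular =
      one_sided_higher(grad$fmi_parallel_values,
                       grad$fmi_perpendicular_values),
    fmi_gradient_perpendicular_near_zero =
      abs(grad$fmi_perpendicular) <= near_zero_epsilon,
    fmi_controls_near_zero =
      all(vapply(ctrls, function(r)
        abs(r$fmi_parallel) <= near_zero_epsilon &&
          abs(r$fmi_perpendicular) <= near_zero_epsilon, logical(1)))
  )
  structure(
    list(verdict = all(crit), criteria = crit, alpha = alpha,
         near_zero_epsilon = near_zero_epsilon,
         gradient_label = gradient_label, control_labels = control_labels),
    class = "chemotaxis_verdict"
  )
}

#' @export
print.chemotaxis_verdict <- function(x, ...) {
  cat(sprintf("Chemotaxis verdict: %s (alpha = %g, epsilon = %g)\n",
              if (x$verdict) "CHEMOTACTIC" else "not chemotactic",
              x$alpha, x$near_zero_epsilon))
  for (nm in names(x$criteria)) {
    cat(sprintf("  [%s] %s\n", if (x$criteria[[nm]]) "pass" else "FAIL", nm))
  }
  invisible(x)
}

#' Two-group and many-group nonparametric comparisons
#'
#' Thin wrappers over the base Mann-Whitney and Kruskal-Wallis tests, the
#' comparisons used for all cohort contrasts (alpha fixed at 0.05 by
#' convention throughout this workflow).  `compare_groups` reports the
#' Mann-Whitney U statistic of the first group and a two-sided p-value
#' (exact for small tie-free samples, normal approximation otherwise, as in
#' [stats::wilcox.test()]).
#'
#' @param values_a,values_b Per-cell metric vectors, each of length >= 2.
#' @param alternative Alternative hypothesis, as in [stats::wilcox.test()].
#' @return `compare_groups`: list with `U`, `p.value`, and the underlying
#'   `htest`.
#' @export
compare_groups <- function(values_a, values_b, alternative = "two.sided") {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("insufficient data: each group needs >= 2 values", call. = FALSE)
  }
  ht <- suppressWarnings(wilcox.test(values_a, values_b,
                                     alternative = alternative))
  list(U = unname(ht$statistic), p.value = ht$p.value, htest = ht)
}

#' @rdname compare_groups
#' @param value_lists A list of >= 2 numeric vectors, each of length >= 2.
#' @return `compare_many`: list with `H`, `p.value`, and the underlying
#'   `htest`.
#' @export
compare_many <- function(value_lists) {
  stopifnot(is.list(value_lists), length(value_lists) >= 2L)
  if (any(vapply(value_lists, length, integer(1)) < 2L)) {
    stop("insufficient data: each group needs >= 2 values", call. = FALSE)
  }
  ht <- kruskal.test(value_lists)
  list(H = unname(ht$statistic), p.value = ht$p.value, htest = ht)
}
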