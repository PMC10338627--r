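#' Relative expression by the delta-delta-Ct method
#'
#' Per replicate: `dCt = Ct_target - Ct_housekeeping` within each condition,
#' `ddCt = dCt_treated - dCt_control`, and fold change `2^(-ddCt)`.
#' Replicates missing any of the four Ct values are excluded with a warning.
#' The computation is invariant to adding a constant to all four Ct values.
#'
#' @param table A data frame (e.g. from [simulate_ct_table()]) with columns
#'   `ct_target_treated`, `ct_housekeeping_treated`, `ct_target_control`,
#'   `ct_housekeeping_control`; one row per replicate.
#' @return List of class `ddct`: per-replicate data frame `replicates`
#'   (`ddct`, `fold_change`), `fold_change` (geometric mean over
#'   replicates), `fold_change_mean` (arithmetic mean), `n`.
#' @export
delta_delta_ct <- function(table) {
  need <- c("ct_target_treated", "ct_housekeeping_treated",
            "ct_target_control", "ct_housekeeping_control")
  stopifnot(is.data.frame(table))
  if (!all(need %in% names(table))) {
    stop("Ct table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ok <- complete.cases(table[need])
  if (any(!ok)) {
    warning(sprintf("%d replicate(s) with missing Ct values excluded",
                    sum(!ok)), call. = FALSE)
  }
  tb <- table[ok, need, drop = FALSE]
  if (nrow(tb) == 0L) {
    stop("insufficient data: no complete replicates", call. = FALSE)
  }
  if (any(tb <= 0) || any(!is.finite(as.matrix(tb)))) {
    stop("Ct values must be finite and > 0", call. = FALSE)
  }
  dct_treated <- tb$ct_target_treated - tb$ct_housekeeping_treated
  dct_control <- tb$ct_target_control - tb$ct_housekeeping_control
  ddct <- dct_treated - dct_control
  fold <- 2^(-ddct)
  structure(
    list(replicates = data.frame(ddct = ddct, fold_change = fold),
         fold_change = 2^(-mean(ddct)), fold_change_mean = mean(fold),
         n = length(ddct)),
    class = "ddct"
  )
}

#' @export
print.ddct <- function(x, ...) {
  cat(sprintf(
    "ddCt fold change: %.4g (geometric mean over %d replicates)\n",
    x$fold_change, x$n))
  invisible(x)
}

#' NanoString positive-control normalization
#'
#' Scales each sample by (mean positive-control total across samples) /
#' (that sample's positive-control total), removing lane-to-lane loading
#' variation.  Raw counts below 40 are flagged undetected *before* scaling;
#' a raw count of exactly 40 is retained.  Samples with a zero
#' positive-control total cannot be scaled and are excluded with an error
#' record.
#'
#' @param counts Nonnegative integer matrix, genes by samples, with row and
#'   column names.
#' @param positive_controls Character vector of positive-control gene
#'   (row) names, or a logical/integer row index.
#' @param undetected_threshold Raw-count threshold below which a
#'   measurement is undetected (default 40).
#' @return List of class `nanostring_norm`: `normalized` matrix,
#'   logical `undetected` mask (same shape), numeric `size_factors`
#'   (per retained sample), character `excluded_samples`.
#' @export
nanostring_normalize <- function(counts, positive_controls,
                                 undetected_threshold = 40) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (is.character(positive_controls)) {
    miss <- setdiff(positive_controls, rownames(counts))
    if (length(miss)) {
      stop("unknown positive-control genes: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    pc <- rownames(counts) %in% positive_controls
  } else {
    pc <- positive_controls
  }
  pc_tot <- colSums(counts[pc, , drop = FALSE])
  bad <- pc_tot <= 0
  excluded <- colnames(counts)[bad]
  if (any(bad)) {
    warning("excluded sample(s) with zero positive-control total: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  }
  counts_ok <- counts[, !bad, drop = FALSE]
  pc_tot <- pc_tot[!bad]
  undetected <- counts_ok < undetected_threshold
  size_factors <- mean(pc_tot) / pc_tot
  normalized <- sweep(counts_ok, 2L, size_factors, `*`)
  structure(
    list(normalized = normalized, undetected = undetected,
         size_factors = setNames(size_factors, colnames(counts_ok)),
         excluded_samples = excluded),
    class = "nanostring_norm"
  )
}

#' Per-cell fluorescence summaries
#'
#' `integrated_density` is the sum of the fluorescence intensities of all
#' pixels of a defined cell (IntDen); `mean_fluorescent_intensity` is the
#' average per pixel (MFI).  Identically, `MFI * pixel count == IntDen`.
#' Exposure time is metadata only: intensities acquired at different
#' exposures are not rescaled or made comparable.
#'
#' @param pixel_intensities Nonnegative numeric vector, one value per pixel,
#'   at least one pixel.
#' @return A scalar in the same arbitrary fluorescence units.
#' @export
integrated_density <- function(pixel_intensities) {
  stopifnot(is.numeric(pixel_intensities))
  if (length(pixel_intensities) < 1L || anyNA(pixel_intensities)) {
    stop("insufficient data: need >= 1 finite pixel intensity",
         call. = FALSE)
  }
  if (any(pixel_intensities < 0)) {
    stop("pixel intensities must be >= 0", call. = FALSE)
  }
  sum(pixel_intensities)
}

#' @rdname integrated_density
#' @export
mean_fluorescent_intensity <- function(pixel_intensities) {
  integrated_density(pixel_intensities) / length(pixel_intensities)
}

#' Positivity percentage from counts
#'
#' The percentage of marker-positive cells among all scored cells, e.g.
#' vimentin positivity of an imaged population.  Reports both the exact
#' percentage and the nearest-integer rounding used in figure legends.
#'
#' @param n_positive,n_total Nonnegative counts with
#'   `0 <= n_positive <= n_total` and `n_total > 0`.
#' @return List with `percent` (exact) and `percent_rounded` (nearest
#'   integer).
#' @examples
#' positivity_fraction(120, 123)$percent_rounded  # 98
#' @export
positivity_fraction <- function(n_positive, n_total) {
  stopifnot(is_number(n_positive), is_number(n_total))
  if (n_total <= 0) {
    stop("insufficient data: n_total must be > 0", call. = FALSE)
  }
  if (n_positive < 0 || n_positive > n_total) {
    stop("n_positive must lie in [0, n_total]", call. = FALSE)
  }
  pct <- 100 * n_positive / n_total
  list(percent = pct, percent_rounded = round(pct))
}

#' Anoikis-resistance ratio
#'
#' Viability (or absorbance) of suspension-challenged cells divided by that
#' of adherent positive-control cells.  An optional common background is
#' subtracted from both signals first.
#'
#' @param challenged_signal Signal of the low-adhesion-challenged cells.
#' @param control_signal Signal of the normal-adhesion control (> background).
#' @param background Optional background signal subtracted from both.
#' @return Nonnegative ratio.
#' @export
anoikis_resistance <- function(challenged_signal, control_signal,
                               background = 0) {
  stopifnot(is_number(challenged_signal), is_number(control_signal),
            is_number(background))
  ctrl <- control_signal - background
  if (ctrl <= 0) {
    stop("undefined ratio: control signal must exceed background",
         call. = FALSE)
  }
  max((challenged_signal - background) / ctrl, 0)
}

#' Densitometry ratio of a western-blot band
#'
#' Band density over loading-control density, optionally renormalized so a
#' declared reference lane equals 1 (batch mode over several lanes).
#'
#' @param band_density Band densities (one or more lanes).
#' @param loading_control_density Loading-control densities, same length,
#'   all > 0.
#' @param reference_lane Optional lane index; when given, all lane ratios
#'   are divided by the reference lane's ratio.
#' @return Numeric vector of ratios.
#' @export
densitometry_ratio <- function(band_density, loading_control_density,
                               reference_lane = NULL) {
  stopifnot(is.numeric(band_density), is.numeric(loading_control_density),
            length(band_density) == length(loading_control_density))
  if (any(loading_control_density <= 0)) {
    stop("undefined ratio: loading control density must be > 0",
         call. = FALSE)
  }
  ratio <- band_density / loading_control_density
  if (!is.null(reference_lane)) {
    stopifnot(is_count(reference_lane),
              reference_lane <= length(ratio))
    if (ratio[reference_lane] == 0) {
      stop("undefined ratio: reference lane has zero ratio", call. = FALSE)
    }
    ratio <- ratio / ratio[reference_lane]
  }
  ratio
}
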