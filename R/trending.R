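#' Consecutive within-subject changes for both monitors
#'
#' For each subject, differences one variable between consecutive available
#' time points in the order baseline, rosc15, rosc30, rosc60, per monitor.
#' Gaps are bridged: if a middle time point is missing, the change spans it.
#' Subjects with fewer than two QC-passed time points contribute nothing.
#'
#' @inheritParams pair_differences
#' @return A tibble: `subject_id`, `from_timepoint`, `to_timepoint`,
#'   `delta_ref`, `delta_test` (later minus earlier, per method).
#' @export
consecutive_changes <- function(pairs, variable = "ci") {
  d <- usable_pairs(pairs, variable)
  d |>
    dplyr::arrange(.data$subject_id, .data$timepoint) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::reframe(
      from_timepoint = as.character(.data$timepoint[-dplyr::n()]),
      to_timepoint = as.character(.data$timepoint[-1]),
      delta_ref = diff(.data$ref),
      delta_test = diff(.data$test)
    )
}

#' Transform paired changes to polar coordinates
#'
#' Each pair of changes (delta_ref, delta_test) becomes a vector whose angle
#' measures the deviation from perfect trend concurrence: the 45-degree
#' identity line of the change-change plane is the polar axis (0 degrees).
#' Points whose mean change is negative are rotated by 180 degrees onto the
#' upper half circle (the half-circle convention), so the angle lies in
#' (-90, +90]. The radius is the absolute mean of the two changes, in the
#' variable's units; a zero mean change gives radius 0 and, by convention,
#' angle 0 when both deltas are zero.
#'
#' @param deltas Output of [consecutive_changes()] (any tibble with
#'   `delta_ref` and `delta_test`).
#' @return The input with `angle_deg` and `radius` columns appended.
#' @examples
#' polar_transform(tibble::tibble(delta_ref = 2, delta_test = 1))
#' # angle -18.43 degrees, radius 1.5
#' @export
polar_transform <- function(deltas) {
  d <- tibble::as_tibble(deltas)
  s <- (d$delta_ref + d$delta_test) / 2
  neg <- s < 0
  dr <- ifelse(neg, -d$delta_ref, d$delta_ref)
  dt <- ifelse(neg, -d$delta_test, d$delta_test)
  angle <- atan2(dt, dr) * 180 / pi - 45
  angle[angle <= -90] <- angle[angle <= -90] + 180
  zero <- d$delta_ref == 0 & d$delta_test == 0
  angle[zero] <- 0
  d$angle_deg <- angle
  d$radius <- abs(s)
  d
}

#' Central exclusion-zone threshold for the polar plot
#'
#' Changes smaller than a fraction (default 10 %) of the overall
#' reference-method mean are too small to judge trending and are excluded.
#' The threshold is that fraction of the reference mean over QC-passed
#' pairs, or an explicit absolute value if supplied.
#'
#' @inheritParams pair_differences
#' @param fraction Fraction of the reference-method mean. Default 0.10.
#' @param absolute Optional absolute threshold in the variable's units;
#'   overrides `fraction`.
#' @return A single threshold in the variable's units.
#' @export
exclusion_threshold <- function(pairs, variable = "ci", fraction = 0.10,
                                absolute = NULL) {
  if (!is.null(absolute)) return(absolute)
  d <- usable_pairs(pairs, variable)
  if (!nrow(d)) abort("no usable pairs to compute an exclusion threshold")
  m <- mean(d$ref)
  if (!is.finite(m) || m <= 0) {
    abort("exclusion threshold undefined: non-positive reference mean")
  }
  fraction * m
}

#' Polar-plot trending statistics
#'
#' Excludes points whose radius falls strictly below the exclusion
#' threshold, then reports the arithmetic mean of the signed angles (the
#' mean angular deviation from the polar axis) and the concordance rate:
#' the percentage of included points within +/- `limit_deg` of the axis
#' (boundary inclusive). Good trending ability requires at least 95 % of
#' points within +/- 30 degrees.
#'
#' @param points Output of [polar_transform()].
#' @param limit_deg Concordance band half-width in degrees. Default 30.
#' @param threshold Exclusion-zone radius (variable units). Default 0.
#' @return A one-row tibble: `n_deltas`, `n_included`, `n_excluded`,
#'   `mean_angular_deviation`, `concordance_pct`, `limit_deg`,
#'   `exclusion_threshold`, `good_trending`. With zero included points the
#'   statistics are `NA` and only the counts are informative.
#' @export
polar_statistics <- function(points, limit_deg = 30, threshold = 0) {
  pts <- tibble::as_tibble(points)
  included <- pts$radius >= threshold
  n_inc <- sum(included)
  if (n_inc == 0) {
    mad <- NA_real_; conc <- NA_real_; good <- NA
  } else {
    a <- pts$angle_deg[included]
    mad <- mean(a)
    conc <- 100 * mean(abs(a) <= limit_deg)
    good <- conc >= 95
  }
  tibble::tibble(
    n_deltas = nrow(pts),
    n_included = n_inc,
    n_excluded = nrow(pts) - n_inc,
    mean_angular_deviation = mad,
    concordance_pct = conc,
    limit_deg = limit_deg,
    exclusion_threshold = threshold,
    good_trending = good
  )
}

#' Full trending analysis for one variable
#'
#' Composes [consecutive_changes()], [polar_transform()],
#' [exclusion_threshold()] and [polar_statistics()].
#'
#' @inheritParams exclusion_threshold
#' @inheritParams polar_statistics
#' @return An object of class `coagree_trend`: a list with `points` (polar
#'   points with an `included` column) and `summary` (the
#'   [polar_statistics()] row).
#' @export
trend_analysis <- function(pairs, variable = "ci", fraction = 0.10,
                           absolute = NULL, limit_deg = 30) {
  deltas <- consecutive_changes(pairs, variable)
  pts <- polar_transform(deltas)
  thr <- exclusion_threshold(pairs, variable, fraction, absolute)
  summ <- polar_statistics(pts, limit_deg, thr)
  pts$included <- pts$radius >= thr
  structure(list(points = pts, summary = summ, variable = variable),
            class = "coagree_trend")
}

#' @export
print.coagree_trend <- function(x, ...) {
  s <- x$summary
  cat("<coagree_trend> variable:", x$variable, "\n")
  cat(sprintf("  %d changes, %d included (exclusion radius < %.3g)\n",
              s$n_deltas, s$n_included, s$exclusion_threshold))
  if (s$n_included > 0) {
    cat(sprintf("  mean angular deviation: %.1f deg\n",
                s$mean_angular_deviation))
    cat(sprintf("  concordance within +/-%g deg: %.1f%% (good trending: %s)\n",
                s$limit_deg, s$concordance_pct, s$good_trending))
  }
  invisible(x)
}
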