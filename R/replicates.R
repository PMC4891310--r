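#' Resolve replicate readings to one summary per monitor and time point
#'
#' Thermodilution yields a short series of replicate injections per
#' (subject, time point); the first pair of consecutive replicates whose CI
#' readings agree to within the policy's discrepancy limit is averaged. The
#' pulse-contour (test) monitor's readings are averaged over its first two
#' replicates without a discrepancy scan, mirroring the study protocol.
#' All other variables are averaged over the same chosen replicates, since
#' those are the injections retained.
#'
#' The relative discrepancy between replicates a and b is
#' |a - b| / mean(a, b). Scanning proceeds over overlapping consecutive
#' pairs (1,2), (2,3), ... up to `max_replicate_draws` replicates; a group
#' with a single replicate resolves to that value. If no pair agrees the
#' group is reported with `resolved = FALSE` (a status, not an error), and
#' the first two replicates are averaged as a placeholder summary.
#'
#' @param records A tibble of measurement records (see [read_measurements()]).
#' @param policy A [qc_policy()].
#' @return One row per (subject, timepoint, method): resolved values of all
#'   hemodynamic variables plus `dpdt`, the number of replicates seen, the
#'   1-based indices of the replicates used, and a logical `resolved`.
#' @examples
#' rec <- tibble::tibble(
#'   subject_id = "S1", timepoint = "baseline", method = "reference",
#'   replicate_index = 1:2, ci = c(4.0, 4.2), svi = NA_real_,
#'   svri = NA_real_, svv = NA_real_, hr = NA_real_, sbp = NA_real_,
#'   dpdt = NA_real_
#' )
#' resolve_replicates(rec)$ci  # 4.1
#' @export
resolve_replicates <- function(records, policy = qc_policy()) {
  stopifnot(inherits(policy, "qc_policy"))
  vars <- c(HEMO_VARS, "dpdt")
  df <- tibble::as_tibble(records)
  df$timepoint <- timepoint_factor(as.character(df$timepoint))

  df <- df |>
    dplyr::arrange(.data$subject_id, .data$timepoint, .data$method,
                   .data$replicate_index) |>
    dplyr::group_by(.data$subject_id, .data$timepoint, .data$method) |>
    dplyr::mutate(
      .row = dplyr::row_number(),
      .scan = .data$method %in% policy$discrepancy_methods,
      .pass = .data$.row >= 2 &
        .data$.row <= policy$max_replicate_draws &
        !is.na(.data$ci) & !is.na(dplyr::lag(.data$ci)) &
        abs(.data$ci - dplyr::lag(.data$ci)) /
          ((.data$ci + dplyr::lag(.data$ci)) / 2) <=
          policy$replicate_discrepancy_limit
    )

  ## Index (within the ordered series) of the second member of the first
  ## agreeing consecutive pair, per scanned group.
  first_pass <- df |>
    dplyr::filter(.data$.scan, .data$.pass) |>
    dplyr::summarise(
      .end_pass = if (dplyr::n()) min(.data$.row) else NA_integer_,
      .groups = "drop"
    )

  meta <- df |>
    dplyr::summarise(n_replicates = dplyr::n(),
                     .scan = .data$.scan[1], .groups = "drop") |>
    dplyr::left_join(first_pass,
                     by = c("subject_id", "timepoint", "method")) |>
    dplyr::mutate(
      resolved = !.data$.scan | .data$n_replicates == 1 |
        !is.na(.data$.end_pass),
      .end = dplyr::case_when(
        n_replicates == 1 ~ 1L,
        .scan & !is.na(.end_pass) ~ as.integer(.end_pass),
        TRUE ~ 2L
      ),
      .start = pmax(1L, .data$.end - 1L),
      replicates_used = ifelse(.data$.end == 1L, "1",
                               paste(.data$.start, .data$.end, sep = ","))
    )

  values <- df |>
    dplyr::ungroup() |>
    dplyr::inner_join(
      dplyr::select(meta, "subject_id", "timepoint", "method",
                    ".start", ".end"),
      by = c("subject_id", "timepoint", "method")
    ) |>
    dplyr::filter(.data$.row >= .data$.start, .data$.row <= .data$.end) |>
    dplyr::group_by(.data$subject_id, .data$timepoint, .data$method) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(vars),
                    ~ ifelse(all(is.na(.x)), NA_real_,
                             mean(.x, na.rm = TRUE))),
      .groups = "drop"
    )

  meta |>
    dplyr::select("subject_id", "timepoint", "method", "n_replicates",
                  "replicates_used", "resolved") |>
    dplyr::left_join(values, by = c("subject_id", "timepoint", "method")) |>
    dplyr::relocate(dplyr::all_of(vars), .after = "method")
}
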