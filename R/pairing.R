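#' Pair the two monitors and apply the measurement rejection rules
#'
#' Resolves replicates (see [resolve_replicates()]), joins the reference and
#' test monitor summaries per (subject, time point), and applies the
#' measurement-level rejection rules:
#'
#' * `sbp_discrepancy` — the two monitors' systolic pressures differ by more
#'   than the policy limit, relative to the reference monitor;
#' * `dpdt_exceeded` — the subject's baseline test-monitor dP/dt exceeds the
#'   policy limit (possible waveform resonance); the flag is set on *all* of
#'   that subject's pairs;
#' * `replicate_unresolved` — either monitor's replicate series could not be
#'   resolved within the policy's draw limit.
#'
#' Flagged pairs are retained but marked, so every rejection is auditable
#' and reversible; `qc_pass` is `TRUE` only when no flag is set, and only
#' `qc_pass` pairs enter the downstream statistics.
#'
#' @param records A tibble of measurement records.
#' @param policy A [qc_policy()].
#' @return A tibble with one row per (subject, timepoint) present for both
#'   methods: columns `<var>_ref` and `<var>_test` for ci, svi, svri, svv,
#'   hr, sbp, plus `dpdt_test`, the three logical flag columns, and
#'   `qc_pass`. Time points observed by only one monitor are dropped with a
#'   warning.
#' @export
pair_and_filter <- function(records, policy = qc_policy()) {
  resolved <- resolve_replicates(records, policy)

  wide <- tidyr::pivot_wider(
    resolved,
    id_cols = c("subject_id", "timepoint"),
    names_from = "method",
    values_from = c(dplyr::all_of(c(HEMO_VARS, "dpdt")), "resolved"),
    names_glue = "{.value}_{method}"
  )

  unmatched <- is.na(wide$ci_reference) | is.na(wide$ci_test)
  if (any(unmatched)) {
    warn(paste0(
      sum(unmatched), " (subject, timepoint) group(s) observed by only one ",
      "method were skipped: ",
      paste(utils::head(paste0(wide$subject_id[unmatched], "/",
                               wide$timepoint[unmatched]), 5),
            collapse = ", ")
    ))
    wide <- wide[!unmatched, ]
  }
  if (!nrow(wide)) abort("no (subject, timepoint) group has both methods")

  names(wide) <- sub("_reference$", "_ref", names(wide))

  ## dP/dt rule: a baseline exceedance flags the whole subject.
  base_dpdt <- wide |>
    dplyr::filter(.data$timepoint == "baseline") |>
    dplyr::mutate(dpdt_subject_flag = !is.na(.data$dpdt_test) &
                    .data$dpdt_test > policy$dpdt_limit) |>
    dplyr::select("subject_id", "dpdt_subject_flag")

  wide |>
    dplyr::left_join(base_dpdt, by = "subject_id") |>
    dplyr::mutate(
      sbp_discrepancy = !is.na(.data$sbp_ref) & !is.na(.data$sbp_test) &
        abs(.data$sbp_ref - .data$sbp_test) / .data$sbp_ref >
          policy$sbp_discrepancy_limit,
      dpdt_exceeded = dplyr::coalesce(.data$dpdt_subject_flag, FALSE),
      replicate_unresolved = !.data$resolved_ref | !.data$resolved_test,
      qc_pass = !.data$sbp_discrepancy & !.data$dpdt_exceeded &
        !.data$replicate_unresolved
    ) |>
    dplyr::select(-"dpdt_subject_flag", -"resolved_ref", -"resolved_test",
                  -"dpdt_ref") |>
    dplyr::arrange(.data$subject_id, .data$timepoint)
}

#' Summarise the quality-control outcome
#'
#' Counts how many paired samples each rejection rule removed, so the
#' removed counts plus the analysis-ready count reconcile exactly with the
#' number of pairs formed.
#'
#' @param pairs Output of [pair_and_filter()].
#' @return A one-row tibble of counts.
#' @export
qc_summary <- function(pairs) {
  tibble::tibble(
    n_pairs = nrow(pairs),
    n_sbp_discrepancy = sum(pairs$sbp_discrepancy),
    n_dpdt_exceeded = sum(pairs$dpdt_exceeded),
    n_replicate_unresolved = sum(pairs$replicate_unresolved),
    n_flagged = sum(!pairs$qc_pass),
    n_analysis = sum(pairs$qc_pass)
  )
}
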