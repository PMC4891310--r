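#' Run the full monitor-agreement analysis
#'
#' Orchestrates the pipeline on raw measurement records: replicate
#' resolution and QC pairing, per-variable Bland-Altman agreement and
#' paired comparisons (overall and per time point), the heart-rate
#' back-calculation comparison, and the polar-plot trending analysis of
#' cardiac index. Strata with too few pairs are reported as unavailable,
#' never silently dropped. The result is deterministic given the input.
#'
#' @param records A tibble of measurement records (see
#'   [read_measurements()] / [simulate_measurements()]).
#' @param policy A [qc_policy()].
#' @param variables Variables to analyse. Default ci, svi, svri, svv.
#' @param orientation Difference orientation, see [pair_differences()].
#' @param min_pairs_agreement,min_pairs_comparison Minimum usable pairs per
#'   stratum for the agreement statistics (default 2) and the paired tests
#'   (default 3).
#' @param exclusion_fraction Central exclusion-zone fraction for the
#'   trending analysis. Default 0.10.
#' @param polar_limit_deg Concordance band half-width. Default 30.
#' @param pe_limit Percentage-error acceptability bound. Default 30.
#' @return An object of class `coagree_report`: a list with `pairs`, `qc`
#'   (counts per rejection rule), `agreement`, `comparison`, `hr_backcalc`,
#'   `trending` (a `coagree_trend` for CI), and `provenance`.
#' @export
run_analysis <- function(records,
                         policy = qc_policy(),
                         variables = c("ci", "svi", "svri", "svv"),
                         orientation = "ref_minus_test",
                         min_pairs_agreement = 2,
                         min_pairs_comparison = 3,
                         exclusion_fraction = 0.10,
                         polar_limit_deg = 30,
                         pe_limit = 30) {
  if (!nrow(records)) abort("empty dataset")
  pairs <- pair_and_filter(records, policy)
  qc <- qc_summary(pairs)
  if (qc$n_analysis == 0) {
    abort(paste0(
      "no analysis-ready pairs left after QC: of ", qc$n_pairs, " pairs, ",
      qc$n_sbp_discrepancy, " flagged sbp_discrepancy, ",
      qc$n_dpdt_exceeded, " flagged dpdt_exceeded, ",
      qc$n_replicate_unresolved, " flagged replicate_unresolved"
    ))
  }

  strata <- c("overall", TIMEPOINTS)
  agreement <- agreement_table(pairs, variables, strata,
                               orientation = orientation,
                               min_pairs = min_pairs_agreement,
                               pe_limit = pe_limit)
  comparison <- purrr::map_dfr(variables, function(v) {
    purrr::map_dfr(strata, function(s) {
      if (nrow(usable_pairs(pairs, v, s)) < min_pairs_comparison) {
        return(tibble::tibble(variable = v, stratum = s,
                              n = nrow(usable_pairs(pairs, v, s)),
                              available = FALSE))
      }
      dplyr::mutate(paired_comparison(pairs, v, s, orientation = orientation),
                    available = TRUE)
    })
  })

  hr_bc <- if (sum(pairs$qc_pass) >= min_pairs_comparison) {
    hr_backcalc_comparison(pairs, orientation = orientation)
  } else NULL

  trending <- if (sum(pairs$qc_pass) >= min_pairs_agreement) {
    trend_analysis(pairs, "ci", fraction = exclusion_fraction,
                   limit_deg = polar_limit_deg)
  } else NULL

  structure(
    list(
      pairs = pairs,
      qc = qc,
      agreement = agreement,
      comparison = comparison,
      hr_backcalc = hr_bc,
      trending = trending,
      provenance = list(
        package_version = as.character(utils::packageVersion("coagree")),
        policy = unclass(policy),
        orientation = orientation,
        n_records = nrow(records),
        timestamp = format(Sys.time(), tz = "UTC")
      )
    ),
    class = "coagree_report"
  )
}

#' @export
print.coagree_report <- function(x, ...) {
  cat("<coagree_report>\n")
  cat(sprintf("  %d records -> %d pairs, %d analysis-ready\n",
              x$provenance$n_records, x$qc$n_pairs, x$qc$n_analysis))
  ov <- dplyr::filter(x$agreement, .data$stratum == "overall",
                      .data$available)
  for (i in seq_len(nrow(ov))) {
    cat(sprintf(
      "  %-4s bias %.3g, LoA [%.3g, %.3g], percentage error %.1f%%\n",
      ov$variable[i], ov$bias[i], ov$loa_lo[i], ov$loa_hi[i],
      ov$pct_error[i]))
  }
  if (!is.null(x$trending)) {
    s <- x$trending$summary
    cat(sprintf("  CI trending: %.1f%% concordance within +/-%g deg (n = %d)\n",
                s$concordance_pct, s$limit_deg, s$n_included))
  }
  invisible(x)
}

#' @rdname run_analysis
#' @param x A `coagree_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.coagree_report <- function(x, ...) {
  agr <- x$agreement
  if (!is.null(x$hr_backcalc)) {
    agr <- dplyr::bind_rows(agr,
                            dplyr::mutate(x$hr_backcalc$agreement,
                                          available = TRUE))
  }
  cmp <- x$comparison
  if (!is.null(x$hr_backcalc)) {
    cmp <- dplyr::bind_rows(cmp,
                            dplyr::mutate(x$hr_backcalc$comparison,
                                          available = TRUE))
  }
  dplyr::left_join(
    agr,
    dplyr::select(cmp, "variable", "stratum", "location_test", "location_p",
                  "correlation_method", "r", "correlation_p"),
    by = c("variable", "stratum")
  )
}

#' @rdname run_analysis
#' @exportS3Method generics::glance
glance.coagree_report <- function(x, ...) {
  ov <- dplyr::filter(x$agreement, .data$variable == "ci",
                      .data$stratum == "overall")
  out <- tibble::tibble(
    n_pairs = x$qc$n_pairs,
    n_analysis = x$qc$n_analysis,
    ci_bias = ov$bias,
    ci_loa_lo = ov$loa_lo,
    ci_loa_hi = ov$loa_hi,
    ci_pct_error = ov$pct_error
  )
  if (!is.null(x$trending)) {
    out$trending_concordance_pct <- x$trending$summary$concordance_pct
    out$mean_angular_deviation <- x$trending$summary$mean_angular_deviation
  }
  out
}

#' Write a report to tidy CSV files
#'
#' Emits `agreement.csv`, `comparison.csv`, `qc.csv`,
#' `ba_coordinates.csv` (plot-ready Bland-Altman pair mean / pair
#' difference per variable) and `polar_points.csv`. Output is byte-stable:
#' identical input gives identical files (no timestamps).
#'
#' @param report A `coagree_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "coagree_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(tidy(report), file.path(dir, "agreement.csv"), na = "")
  readr::write_csv(report$comparison, file.path(dir, "comparison.csv"),
                   na = "")
  readr::write_csv(report$qc, file.path(dir, "qc.csv"), na = "")

  vars <- unique(report$agreement$variable)
  coords <- purrr::map_dfr(vars, function(v) {
    up <- usable_pairs(report$pairs, v)
    if (nrow(up) < 2) return(NULL)
    d <- pair_differences(report$pairs, v,
                          orientation = report$provenance$orientation)
    dplyr::mutate(
      dplyr::select(d, "subject_id", "timepoint", "mean", "diff"),
      variable = v, timepoint = as.character(.data$timepoint),
      .before = 1
    )
  })
  readr::write_csv(coords, file.path(dir, "ba_coordinates.csv"), na = "")

  if (!is.null(report$trending)) {
    readr::write_csv(report$trending$points,
                     file.path(dir, "polar_points.csv"), na = "")
    readr::write_csv(report$trending$summary,
                     file.path(dir, "trending.csv"), na = "")
  }
  invisible(dir)
}
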