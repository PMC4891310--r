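#' Measurement quality-control policy
#'
#' Bundles the rejection rules applied before any agreement statistic is
#' computed: the replicate-injection discrepancy limit for the reference
#' (thermodilution) series, the inter-monitor systolic-pressure discrepancy
#' limit, and the baseline dP/dt resonance limit for the pulse-contour
#' monitor.
#'
#' @param replicate_discrepancy_limit Maximum relative discrepancy
#'   (|a - b| / mean(a, b)) between two consecutive replicate CI readings for
#'   the pair to be accepted. Default 0.10.
#' @param sbp_discrepancy_limit Maximum relative difference between the two
#'   monitors' systolic pressures (relative to the reference monitor) before
#'   a pair is flagged. Default 0.10.
#' @param dpdt_limit Maximum baseline dP/dt of the test monitor; subjects
#'   exceeding it are flagged for possible waveform resonance. Default 1.7.
#' @param max_replicate_draws Maximum number of replicates scanned when
#'   resolving a replicate series. Default 6.
#' @param discrepancy_methods Methods whose replicate series are subject to
#'   the discrepancy scan. The repeat-injection rule belongs to the
#'   thermodilution reference; the test monitor's two simultaneous readings
#'   are always averaged as-is. Default `"reference"`.
#'
#' @return An object of class `qc_policy` (a named list).
#' @examples
#' qc_policy()
#' qc_policy(sbp_discrepancy_limit = 0.05)
#' @export
qc_policy <- function(replicate_discrepancy_limit = 0.10,
                      sbp_discrepancy_limit = 0.10,
                      dpdt_limit = 1.7,
                      max_replicate_draws = 6L,
                      discrepancy_methods = "reference") {
  limits <- c(
    replicate_discrepancy_limit = replicate_discrepancy_limit,
    sbp_discrepancy_limit = sbp_discrepancy_limit,
    dpdt_limit = dpdt_limit,
    max_replicate_draws = max_replicate_draws
  )
  bad <- names(limits)[!is.finite(limits) | limits <= 0]
  if (length(bad)) {
    abort(paste0("qc_policy limits must be strictly positive: ",
                 paste(bad, collapse = ", ")))
  }
  if (!all(discrepancy_methods %in% c("reference", "test"))) {
    abort("discrepancy_methods must be a subset of c('reference', 'test')")
  }
  structure(
    list(
      replicate_discrepancy_limit = replicate_discrepancy_limit,
      sbp_discrepancy_limit = sbp_discrepancy_limit,
      dpdt_limit = dpdt_limit,
      max_replicate_draws = as.integer(max_replicate_draws),
      discrepancy_methods = discrepancy_methods
    ),
    class = "qc_policy"
  )
}

#' @export
print.qc_policy <- function(x, ...) {
  cat("<qc_policy>\n")
  cat("  replicate discrepancy limit:", x$replicate_discrepancy_limit, "\n")
  cat("  SBP discrepancy limit:      ", x$sbp_discrepancy_limit, "\n")
  cat("  baseline dP/dt limit:       ", x$dpdt_limit, "\n")
  cat("  max replicate draws:        ", x$max_replicate_draws, "\n")
  cat("  discrepancy scan applied to:", paste(x$discrepancy_methods, collapse = ", "), "\n")
  invisible(x)
}
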