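#' Per-pair differences and means for one variable
#'
#' Extracts the QC-passed pairs of one variable and computes the per-pair
#' difference (reference - test by default, matching the usual
#' reference-minus-test table orientation), the per-pair mean, and the
#' per-pair percent difference relative to the reference value.
#'
#' @param pairs Output of [pair_and_filter()] (or any tibble with
#'   `<variable>_ref` / `<variable>_test` columns; rows with `qc_pass ==
#'   FALSE` are dropped when the column is present).
#' @param variable One of `"ci"`, `"svi"`, `"svri"`, `"svv"`, `"hr"`,
#'   `"sbp"` (any suffix pair present in `pairs`).
#' @param orientation `"ref_minus_test"` (default) or `"test_minus_ref"`.
#' @param stratum `"overall"` (default) or a time-point label to subset.
#' @return A tibble with `subject_id`, `timepoint`, `ref`, `test`, `diff`,
#'   `mean`, `pct_diff`.
#' @examples
#' p <- tibble::tibble(subject_id = c("a", "b"), timepoint = "baseline",
#'                     ci_ref = c(4.5, 4.5), ci_test = c(4.0, 4.0),
#'                     qc_pass = TRUE)
#' pair_differences(p, "ci")
#' @export
pair_differences <- function(pairs, variable,
                             orientation = c("ref_minus_test",
                                             "test_minus_ref"),
                             stratum = "overall") {
  orientation <- match.arg(orientation)
  d <- usable_pairs(pairs, variable, stratum)
  if (nrow(d) < 2) {
    abort(paste0("insufficient data: need >= 2 usable pairs for '", variable,
                 "' in stratum '", stratum, "', got ", nrow(d)))
  }
  sgn <- if (orientation == "ref_minus_test") 1 else -1
  dplyr::mutate(
    d,
    diff = sgn * (.data$ref - .data$test),
    mean = (.data$ref + .data$test) / 2,
    pct_diff = 100 * .data$diff / .data$ref
  )
}

## Subset QC-clean, complete pairs of one variable and one stratum.
usable_pairs <- function(pairs, variable, stratum = "overall") {
  rc <- paste0(variable, "_ref")
  tc <- paste0(variable, "_test")
  if (!all(c(rc, tc) %in% names(pairs))) {
    abort(paste0("variable '", variable, "' not present as ", rc, "/", tc))
  }
  d <- tibble::as_tibble(pairs)
  if ("qc_pass" %in% names(d)) d <- d[d$qc_pass, ]
  if (!identical(stratum, "overall")) {
    if (!stratum %in% TIMEPOINTS) abort(paste0("unknown stratum: ", stratum))
    d <- d[as.character(d$timepoint) == stratum, ]
  }
  out <- tibble::tibble(
    subject_id = d$subject_id,
    timepoint = d$timepoint,
    ref = d[[rc]],
    test = d[[tc]]
  )
  out[!is.na(out$ref) & !is.na(out$test), ]
}

#' Bland-Altman agreement statistics for one variable and one stratum
#'
#' Bias is the mean of the per-pair differences; its precision is the
#' sample SD of the differences (n - 1 denominator) with a t-based 95 %
#' confidence interval. Limits of agreement (LoA) are bias +/- 1.96 SD,
#' with 1.96 as a fixed constant. Percentage LoA apply the same construction
#' to the per-pair percent differences relative to the reference method.
#' Each monitor's coefficient of variation is 100 * SD / mean of its own
#' values, and the percentage error is 1.96 SD of the differences over the
#' pooled mean of both methods (see [percentage_error()]).
#'
#' @inheritParams pair_differences
#' @param conf_level Confidence level for the bias CI. Default 0.95.
#' @param pe_limit Acceptability bound for the percentage error. Default 30.
#' @return A one-row tibble: `variable`, `stratum`, `n`, `mean_ref`,
#'   `mean_test`, `bias`, `sd_diff`, `ci_lo`, `ci_hi`, `loa_lo`, `loa_hi`,
#'   `bias_pct`, `loa_lo_pct`, `loa_hi_pct`, `cv_ref`, `cv_test`,
#'   `pct_error`, `acceptable`.
#' @export
bland_altman <- function(pairs, variable, stratum = "overall",
                         orientation = c("ref_minus_test", "test_minus_ref"),
                         conf_level = 0.95, pe_limit = 30) {
  orientation <- match.arg(orientation)
  d <- pair_differences(pairs, variable, orientation, stratum)
  n <- nrow(d)
  bias <- mean(d$diff)
  sd_diff <- sd(d$diff)
  half_ci <- qt(1 - (1 - conf_level) / 2, n - 1) * sd_diff / sqrt(n)
  bias_pct <- mean(d$pct_diff)
  sd_pct <- sd(d$pct_diff)
  mean_ref <- mean(d$ref)
  mean_test <- mean(d$test)
  pe <- percentage_error(sd_diff, mean_ref, mean_test, limit = pe_limit)
  tibble::tibble(
    variable = variable,
    stratum = stratum,
    n = n,
    mean_ref = mean_ref,
    mean_test = mean_test,
    bias = bias,
    sd_diff = sd_diff,
    ci_lo = bias - half_ci,
    ci_hi = bias + half_ci,
    loa_lo = bias - 1.96 * sd_diff,
    loa_hi = bias + 1.96 * sd_diff,
    bias_pct = bias_pct,
    loa_lo_pct = bias_pct - 1.96 * sd_pct,
    loa_hi_pct = bias_pct + 1.96 * sd_pct,
    cv_ref = 100 * sd(d$ref) / mean_ref,
    cv_test = 100 * sd(d$test) / mean_test,
    pct_error = pe$pct_error,
    acceptable = pe$acceptable
  )
}

#' Percentage error of agreement (Critchley criterion)
#'
#' 100 * 1.96 * SD(differences) / pooled mean of the two methods, with an
#' acceptability verdict against the conventional 30 % bound: monitors whose
#' percentage error exceeds the bound are deemed clinically not
#' interchangeable.
#'
#' @param sd_diff SD of the per-pair differences (or a one-row
#'   [bland_altman()] result, from which `sd_diff`, `mean_ref`, `mean_test`
#'   are taken).
#' @param mean_ref,mean_test Mean value of each method.
#' @param limit Acceptability bound in percent. Default 30.
#' @return A one-row tibble: `pct_error`, `limit`, `acceptable`.
#' @examples
#' percentage_error(1, 4.333, 4.333)            # 45.2 %
#' percentage_error(3.45 / 1.96, 4.5, 4.0)      # 81.2 %
#' @export
percentage_error <- function(sd_diff, mean_ref = NULL, mean_test = NULL,
                             limit = 30) {
  if (is.data.frame(sd_diff)) {
    stopifnot(nrow(sd_diff) == 1)
    mean_ref <- sd_diff$mean_ref
    mean_test <- sd_diff$mean_test
    sd_diff <- sd_diff$sd_diff
  }
  pooled <- (mean_ref + mean_test) / 2
  if (!is.finite(pooled) || pooled <= 0) {
    abort("percentage error undefined: pooled mean of both methods is not positive")
  }
  pe <- 100 * 1.96 * sd_diff / pooled
  tibble::tibble(pct_error = pe, limit = limit, acceptable = pe <= limit)
}

#' Agreement table over several variables and strata
#'
#' Runs [bland_altman()] for each variable in each stratum, mirroring the
#' per-time-point agreement tables of monitor-comparison studies. Strata
#' with fewer than `min_pairs` usable pairs are reported with their count
#' and `available = FALSE` rather than silently dropped.
#'
#' @inheritParams bland_altman
#' @param variables Character vector of variables.
#' @param strata Character vector of strata; default overall plus each time
#'   point.
#' @param min_pairs Minimum usable pairs per stratum. Default 2.
#' @return A tibble, one row per variable x stratum, with an `available`
#'   column.
#' @export
agreement_table <- function(pairs, variables = c("ci", "svi", "svri", "svv"),
                            strata = c("overall", TIMEPOINTS),
                            orientation = "ref_minus_test",
                            min_pairs = 2, pe_limit = 30) {
  purrr::map_dfr(variables, function(v) {
    purrr::map_dfr(strata, function(s) {
      n_usable <- nrow(usable_pairs(pairs, v, s))
      if (n_usable < min_pairs) {
        return(tibble::tibble(variable = v, stratum = s, n = n_usable,
                              available = FALSE))
      }
      dplyr::mutate(
        bland_altman(pairs, v, s, orientation = orientation,
                     pe_limit = pe_limit),
        available = TRUE
      )
    })
  })
}
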