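#' Paired comparison with a normality gate
#'
#' Tests each monitor's values for normality with a Kolmogorov-Smirnov test
#' against a normal distribution with moments estimated from the sample, at
#' alpha = 0.05. If both monitors pass, the location comparison is the
#' paired t test and the correlation Pearson's; otherwise the Wilcoxon
#' signed-rank test and Spearman's rank correlation are used. The gate
#' outcome is reported alongside the results so either branch is auditable.
#'
#' @inheritParams pair_differences
#' @param alpha Significance level for the normality gate. Default 0.05.
#' @return A one-row tibble: `variable`, `stratum`, `n`, `normality_p_ref`,
#'   `normality_p_test`, `location_test`, `location_p`, `mean_difference`,
#'   `ci_lo`, `ci_hi` (t-based CI of the mean difference),
#'   `correlation_method`, `r`, `correlation_p`.
#' @export
paired_comparison <- function(pairs, variable, stratum = "overall",
                              orientation = c("ref_minus_test",
                                              "test_minus_ref"),
                              alpha = 0.05) {
  orientation <- match.arg(orientation)
  d <- pair_differences(pairs, variable, orientation, stratum)
  n <- nrow(d)
  if (n < 3) {
    abort(paste0("insufficient data: need >= 3 usable pairs for a paired ",
                 "comparison of '", variable, "', got ", n))
  }
  p_ref <- ks_normal_p(d$ref)
  p_test <- ks_normal_p(d$test)
  normal <- p_ref > alpha && p_test > alpha

  if (normal) {
    location_test <- "paired_t"
    if (sd(d$diff) <= 1e-10 * max(abs(mean(d$diff)), 1)) {
      ## constant differences: no evidence of a shift when zero, certain
      ## shift otherwise (the t statistic is undefined either way)
      location_p <- if (abs(mean(d$diff)) <= 1e-10) 1 else 0
    } else {
      location_p <- t.test(d$diff)$p.value
    }
    cor_method <- "pearson"
  } else {
    if (all(d$diff == d$diff[1])) {
      abort(paste0("degenerate location test: all paired differences are ",
                   "identical (", d$diff[1], ") for '", variable, "'"))
    }
    loc <- suppressWarnings(wilcox.test(d$ref, d$test, paired = TRUE))
    location_test <- "wilcoxon"
    location_p <- loc$p.value
    cor_method <- "spearman"
  }
  ct <- suppressWarnings(cor.test(d$ref, d$test, method = cor_method))

  mean_diff <- mean(d$diff)
  half <- qt(0.975, n - 1) * sd(d$diff) / sqrt(n)
  tibble::tibble(
    variable = variable, stratum = stratum, n = n,
    normality_p_ref = p_ref, normality_p_test = p_test,
    location_test = location_test, location_p = location_p,
    mean_difference = mean_diff,
    ci_lo = mean_diff - half, ci_hi = mean_diff + half,
    correlation_method = cor_method,
    r = unname(ct$estimate), correlation_p = ct$p.value
  )
}

## Kolmogorov-Smirnov p-value against a normal with estimated moments.
## Degenerate (zero-variance) samples are treated as passing the gate:
## a constant reading is not evidence against using the mean-based branch.
ks_normal_p <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(1)
  suppressWarnings(ks.test(x, "pnorm", mean(x), s)$p.value)
}

#' Back-calculate heart rate from indexed cardiac output and stroke volume
#'
#' The internal heart rate a pulse-contour monitor used to convert stroke
#' volume index into cardiac index: HR = CI * 1000 / SVI (CI in L/min/m^2,
#' SVI in mL/m^2, HR in beats/min).
#'
#' @param ci Cardiac index, L/min/m^2.
#' @param svi Stroke volume index, mL/m^2; must be positive.
#' @return Heart rate in beats/min, vectorised over the inputs.
#' @examples
#' back_calculate_hr(3.0, 30)   # 100
#' back_calculate_hr(4.0, 31.2) # 128.2
#' @export
back_calculate_hr <- function(ci, svi) {
  if (any(!is.na(svi) & svi <= 0)) {
    abort("svi must be strictly positive to back-calculate heart rate")
  }
  ci * 1000 / svi
}

#' Compare back-calculated test-monitor heart rate with the reference HR
#'
#' Computes the test monitor's implicit heart rate from its CI and SVI via
#' [back_calculate_hr()], then runs the full paired machinery (agreement
#' and paired comparison) of the reference monitor's measured HR against
#' it. The difference orientation is reference - calculated.
#'
#' @inheritParams bland_altman
#' @return A list with `agreement` (one [bland_altman()] row, variable
#'   `"hr_calc"`) and `comparison` (one [paired_comparison()] row).
#' @export
hr_backcalc_comparison <- function(pairs, stratum = "overall",
                                   orientation = "ref_minus_test") {
  p2 <- tibble::as_tibble(pairs)
  p2$hr_calc_ref <- p2$hr_ref
  p2$hr_calc_test <- back_calculate_hr(p2$ci_test, p2$svi_test)
  list(
    agreement = bland_altman(p2, "hr_calc", stratum,
                             orientation = orientation),
    comparison = paired_comparison(p2, "hr_calc", stratum,
                                   orientation = orientation)
  )
}
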