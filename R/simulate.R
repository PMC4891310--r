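#' Configuration for the synthetic study-design generator
#'
#' Describes a two-monitor cardiac-arrest comparison study: a cohort of
#' subjects observed at baseline, of whom a Bernoulli fraction achieve
#' return of spontaneous circulation (ROSC) and are re-measured at three
#' post-ROSC time points. Each subject carries a latent cardiac-index
#' trajectory (a log-normal baseline level times fixed per-time-point
#' multipliers expressing post-arrest depression with recovery). The
#' reference monitor observes the latent value through multiplicative
#' log-normal replicate noise; the test monitor observes a convex mixture of
#' the latent value and an independent draw (its `fidelity`), rescaled and
#' shifted, through its own larger replicate noise.
#'
#' @param n_subjects Cohort size. Default 24.
#' @param p_rosc Probability a subject achieves ROSC and contributes the
#'   three post-ROSC time points. Default 0.5.
#' @param baseline_ci_mean,baseline_ci_sd Mean and SD (L/min/m^2) of the
#'   log-normal latent baseline cardiac index. Defaults 4.5 and 1.0.
#' @param trajectory_multipliers Named fractions applied to the baseline
#'   latent CI at rosc15/rosc30/rosc60.
#'   Defaults `c(rosc15 = 0.75, rosc30 = 0.85, rosc60 = 0.95)`.
#' @param ref_noise_cv Per-replicate coefficient of variation of the
#'   reference monitor. Default 0.10.
#' @param test_bias Additive shift of the test monitor's signal
#'   (L/min/m^2, applied after scaling; negative means the test monitor
#'   reads lower). Default -0.5.
#' @param test_scale Multiplicative scale of the test monitor's signal.
#'   Default 1.
#' @param test_noise_cv Per-replicate CV of the test monitor. Default 0.25.
#' @param fidelity Weight in \[0, 1\] of the true latent value in the test
#'   monitor's signal; the remainder is an independent latent draw, so lower
#'   fidelity decorrelates the monitors. Default 0.3.
#' @param hr_mean,hr_sd Latent baseline heart rate (beats/min).
#'   Defaults 150 and 20.
#' @param hr_jitter_cv Per-time-point CV of the latent heart rate around the
#'   subject's level. Default 0.05.
#' @param hr_obs_cv Per-replicate CV of each monitor's heart-rate reading.
#'   Default 0.02.
#' @param sbp_mean,sbp_sd Latent systolic pressure (mmHg).
#'   Defaults 90 and 15.
#' @param sbp_jitter_cv Per-monitor CV of the observed systolic pressure
#'   around the latent value (drives the SBP-discrepancy rejection rate).
#'   Default 0.04.
#' @param dpdt_meanlog,dpdt_sdlog Log-normal parameters of the test
#'   monitor's dP/dt; the defaults (log 1.2, 0.272) put roughly 10 % of
#'   subjects above the 1.7 resonance limit.
#' @param svv_mean,svv_cv Latent stroke-volume-variation level (percent) and
#'   its CV. Defaults 17 and 0.3.
#' @param seed Default seed used by [simulate_measurements()]. Default 1.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_subjects = 24L,
                       p_rosc = 0.5,
                       baseline_ci_mean = 4.5,
                       baseline_ci_sd = 1.0,
                       trajectory_multipliers = c(rosc15 = 0.75,
                                                  rosc30 = 0.85,
                                                  rosc60 = 0.95),
                       ref_noise_cv = 0.10,
                       test_bias = -0.5,
                       test_scale = 1.0,
                       test_noise_cv = 0.25,
                       fidelity = 0.3,
                       hr_mean = 150, hr_sd = 20,
                       hr_jitter_cv = 0.05,
                       hr_obs_cv = 0.02,
                       sbp_mean = 90, sbp_sd = 15,
                       sbp_jitter_cv = 0.04,
                       dpdt_meanlog = log(1.2), dpdt_sdlog = 0.272,
                       svv_mean = 17, svv_cv = 0.3,
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  check <- function(ok, field, msg) {
    if (!isTRUE(ok)) abort(paste0("invalid sim_config field '", field, "': ", msg))
  }
  check(is.numeric(cfg$n_subjects) && cfg$n_subjects >= 1,
        "n_subjects", "must be >= 1")
  for (p in c("p_rosc", "fidelity")) {
    check(is.numeric(cfg[[p]]) && cfg[[p]] >= 0 && cfg[[p]] <= 1,
          p, "must lie in [0, 1]")
  }
  for (p in c("ref_noise_cv", "test_noise_cv", "hr_jitter_cv", "hr_obs_cv",
              "sbp_jitter_cv", "svv_cv")) {
    check(is.numeric(cfg[[p]]) && cfg[[p]] >= 0 && cfg[[p]] <= 1,
          p, "must be a CV in [0, 1]")
  }
  for (p in c("baseline_ci_mean", "hr_mean", "sbp_mean", "svv_mean",
              "test_scale")) {
    check(is.numeric(cfg[[p]]) && cfg[[p]] > 0, p, "must be positive")
  }
  for (p in c("baseline_ci_sd", "hr_sd", "sbp_sd", "dpdt_sdlog")) {
    check(is.numeric(cfg[[p]]) && cfg[[p]] >= 0, p, "must be non-negative")
  }
  check(all(trajectory_multipliers > 0) &&
          all(names(trajectory_multipliers) %in% TIMEPOINTS[-1]) &&
          length(trajectory_multipliers) == 3,
        "trajectory_multipliers",
        "must be positive and named rosc15/rosc30/rosc60")
  cfg$n_subjects <- as.integer(cfg$n_subjects)
  cfg
}

#' A fully noiseless identity configuration
#'
#' All noise sources zero, no bias, unit scale, perfect fidelity: both
#' monitors read the latent truth exactly, so every paired sample has
#' `ref == test`. Useful for end-to-end identity checks.
#'
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
noiseless_config <- function(...) {
  args <- modifyList(
    list(ref_noise_cv = 0, test_noise_cv = 0, test_bias = 0, test_scale = 1,
         fidelity = 1, hr_obs_cv = 0, sbp_jitter_cv = 0,
         dpdt_meanlog = log(1), dpdt_sdlog = 0),
    list(...)
  )
  do.call(sim_config, args)
}

## Unit-mean multiplicative log-normal noise with the given CV.
lnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

## Log-normal draws with the given arithmetic mean and CV.
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  mean * lnoise(n, cv)
}

#' Generate a synthetic two-monitor dataset
#'
#' Draws a cohort per the configuration and emits raw measurement records:
#' at least two reference-monitor replicates per (subject, time point), with
#' further replicates drawn (up to six) whenever two consecutive CI readings
#' disagree by more than 10 % — reproducing the repeat-injection protocol —
#' and exactly two test-monitor replicates. Stroke volume index is derived
#' per monitor as 1000·CI/HR so the heart-rate back-calculation identity
#' holds, and SVRI follows the resistance identity from the monitor's own
#' pressure and CI readings. SBP and dP/dt are generated so the
#' SBP-discrepancy and resonance rejection rules fire at realistic rates.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`. The output is
#'   deterministic given the seed.
#' @return A list with class `coagree_sim`: `records` (a measurement
#'   tibble, see [read_measurements()]) and `truth` (latent values and the
#'   ROSC indicator per subject and time point).
#' @export
simulate_measurements <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  cfg <- config
  cvp <- 5          # assumed central venous pressure, mmHg
  map_frac <- 0.75  # mean arterial pressure as a fraction of systolic
  max_draws <- 6L   # repeat-injection cap for the reference series

  n <- cfg$n_subjects
  ids <- sprintf("S%03d", seq_len(n))
  B <- rlnorm_mean_cv(n, cfg$baseline_ci_mean,
                      cfg$baseline_ci_sd / cfg$baseline_ci_mean)
  rosc <- rbinom(n, 1, cfg$p_rosc) == 1
  H <- pmax(40, rnorm(n, cfg$hr_mean, cfg$hr_sd))

  ## One row per (subject, timepoint) actually observed.
  subj <- c(seq_len(n), rep(which(rosc), each = 3))
  tp <- c(rep("baseline", n),
          rep(TIMEPOINTS[-1], times = sum(rosc)))
  ord <- order(subj, match(tp, TIMEPOINTS))
  subj <- subj[ord]; tp <- tp[ord]
  g <- length(subj)
  mult <- ifelse(tp == "baseline", 1,
                 unname(cfg$trajectory_multipliers[tp]))

  L <- B[subj] * mult
  B2 <- rlnorm_mean_cv(g, cfg$baseline_ci_mean,
                       cfg$baseline_ci_sd / cfg$baseline_ci_mean)
  signal <- pmax(0.05,
                 cfg$test_scale * (cfg$fidelity * L +
                                     (1 - cfg$fidelity) * B2 * mult) +
                   cfg$test_bias)
  hr_lat <- H[subj] * lnoise(g, cfg$hr_jitter_cv)
  sbp_lat <- pmax(40, rnorm(g, cfg$sbp_mean, cfg$sbp_sd))
  svv_lat <- pmin(100, rlnorm_mean_cv(g, cfg$svv_mean, cfg$svv_cv))
  dpdt_val <- if (cfg$dpdt_sdlog == 0 && cfg$dpdt_meanlog == 0) rep(1, g) else
    rlnorm(g, cfg$dpdt_meanlog, cfg$dpdt_sdlog)
  sbp_ref <- sbp_lat * lnoise(g, cfg$sbp_jitter_cv)
  sbp_test <- sbp_lat * lnoise(g, cfg$sbp_jitter_cv)

  ## Reference replicates: repeat injections until two consecutive CI
  ## readings agree within 10 %, up to six draws. Candidate readings are
  ## drawn up front; the series is cut at the stopping point.
  ci_ref6 <- matrix(rep(L, each = max_draws) *
                      lnoise(g * max_draws, cfg$ref_noise_cv),
                    nrow = max_draws)
  agree <- abs(ci_ref6[-1, , drop = FALSE] -
                 ci_ref6[-max_draws, , drop = FALSE]) /
    ((ci_ref6[-1, , drop = FALSE] + ci_ref6[-max_draws, , drop = FALSE]) / 2) <=
    0.10
  n_ref <- apply(agree, 2, function(a) {
    k <- which(a)[1]
    if (is.na(k)) max_draws else k + 1L
  })
  ref_g <- rep(seq_len(g), n_ref)
  ref_idx <- sequence(n_ref)
  ci_r <- ci_ref6[cbind(ref_idx, ref_g)]
  hr_r <- hr_lat[ref_g] * lnoise(length(ref_g), cfg$hr_obs_cv)
  ref_rows <- tibble::tibble(
    subject_id = ids[subj[ref_g]], timepoint = tp[ref_g],
    method = "reference", replicate_index = ref_idx,
    ci = ci_r,
    svi = 1000 * ci_r / hr_r,
    svri = pmax(1, 80 * (map_frac * sbp_ref[ref_g] - cvp) / ci_r),
    svv = pmin(100, svv_lat[ref_g] * lnoise(length(ref_g), cfg$ref_noise_cv)),
    hr = hr_r,
    sbp = sbp_ref[ref_g],
    dpdt = NA_real_
  )

  test_g <- rep(seq_len(g), each = 2)
  ci_t <- pmax(0.01, signal[test_g] * lnoise(2 * g, cfg$test_noise_cv))
  hr_t <- hr_lat[test_g] * lnoise(2 * g, cfg$hr_obs_cv)
  test_rows <- tibble::tibble(
    subject_id = ids[subj[test_g]], timepoint = tp[test_g],
    method = "test", replicate_index = rep(1:2, g),
    ci = ci_t,
    svi = 1000 * ci_t / hr_t,
    svri = pmax(1, 80 * (map_frac * sbp_test[test_g] - cvp) / ci_t),
    svv = pmin(100, svv_lat[test_g] * lnoise(2 * g, cfg$test_noise_cv)),
    hr = hr_t,
    sbp = sbp_test[test_g],
    dpdt = dpdt_val[test_g]
  )

  records <- dplyr::bind_rows(ref_rows, test_rows)
  records$timepoint <- timepoint_factor(records$timepoint)
  records <- dplyr::arrange(records, .data$subject_id, .data$timepoint,
                            .data$method, .data$replicate_index)

  truth <- tibble::tibble(
    subject_id = ids[subj], timepoint = timepoint_factor(tp),
    rosc = rosc[subj],
    ci = L, hr = hr_lat, svi = 1000 * L / hr_lat,
    svri = pmax(1, 80 * (map_frac * sbp_lat - cvp) / L),
    svv = svv_lat, sbp = sbp_lat, test_signal = signal
  )
  structure(list(records = records, truth = truth,
                 config = config, seed = as.integer(seed)),
            class = "coagree_sim")
}

#' @export
print.coagree_sim <- function(x, ...) {
  cat("<coagree_sim> ", length(unique(x$records$subject_id)), " subjects, ",
      nrow(x$records), " measurement rows (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Analytic expectations implied by a generator configuration
#'
#' Closed-form population values of the downstream agreement statistics
#' under the generator's algebra, for parameter-recovery testing. The
#' reference-minus-test bias, difference SD, percentage error, pooled means
#' and Pearson correlation are assembled exactly from the configured
#' variance components (latent between-subject and between-time-point
#' spread, each monitor's replicate noise averaged over two replicates, the
#' fidelity mixture, scale and bias), pooling time points with weights
#' (1, p_rosc, p_rosc, p_rosc). The small conditioning effect of the
#' replicate-agreement scan and the positivity clamps is ignored.
#'
#' The expected polar-plot concordance has no convenient closed form; it is
#' computed by direct high-precision Monte Carlo on the consecutive-change
#' distribution (not via the pipeline code), with the RNG state saved and
#' restored.
#'
#' @param config A [sim_config()].
#' @param trending Logical; also compute the expected trending concordance
#'   (Monte Carlo over `n_trend` simulated survivors). Default TRUE.
#' @param n_trend Monte Carlo size for the trending expectation.
#' @return A one-row tibble: `bias`, `sd_diff`, `pct_error`, `mean_ref`,
#'   `mean_test`, `pearson_r`, and (if requested)
#'   `trending_concordance_pct` and `mean_angular_deviation`.
#' @export
expected_summaries <- function(config = sim_config(), trending = TRUE,
                               n_trend = 20000L) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  m <- c(baseline = 1, cfg$trajectory_multipliers[TIMEPOINTS[-1]])
  w <- c(1, rep(cfg$p_rosc, 3))
  w <- w / sum(w)
  mu_t <- cfg$baseline_ci_mean * m
  var_t <- (cfg$baseline_ci_sd * m)^2
  s <- cfg$test_scale; b <- cfg$test_bias; f <- cfg$fidelity
  vr <- cfg$ref_noise_cv^2 / 2   # variance of a unit-mean 2-replicate average
  vt <- cfg$test_noise_cv^2 / 2

  muY <- s * mu_t + b
  varY <- s^2 * (f^2 + (1 - f)^2) * var_t
  ed_t <- mu_t - muY
  vard_t <- (1 - s * f)^2 * var_t + s^2 * (1 - f)^2 * var_t +
    (mu_t^2 + var_t) * vr + (muY^2 + varY) * vt

  bias <- sum(w * ed_t)
  var_d <- sum(w * (vard_t + ed_t^2)) - bias^2
  mean_ref <- sum(w * mu_t)
  mean_test <- sum(w * muY)
  pooled <- (mean_ref + mean_test) / 2
  pct_error <- if (pooled > 0) 100 * 1.96 * sqrt(var_d) / pooled else NA_real_

  cov_xy <- sum(w * (s * f * var_t + mu_t * muY)) - mean_ref * mean_test
  var_x <- sum(w * (var_t * (1 + vr) + mu_t^2 * vr + mu_t^2)) - mean_ref^2
  var_y <- sum(w * (varY * (1 + vt) + muY^2 * vt + muY^2)) - mean_test^2
  pearson_r <- if (var_x > 0 && var_y > 0) cov_xy / sqrt(var_x * var_y)
               else NA_real_

  out <- tibble::tibble(
    bias = bias, sd_diff = sqrt(var_d), pct_error = pct_error,
    mean_ref = mean_ref, mean_test = mean_test, pearson_r = pearson_r
  )
  if (trending) {
    tr <- expected_trending_mc(cfg, mean_ref, as.integer(n_trend))
    out$trending_concordance_pct <- tr$concordance
    out$mean_angular_deviation <- tr$mean_angle
  }
  out
}

## Monte Carlo expectation of the polar-plot statistics, computed directly
## on the generator's delta distribution (independent of the pipeline path).
expected_trending_mc <- function(cfg, mean_ref, n) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(987654L)

  m <- c(1, unname(cfg$trajectory_multipliers[TIMEPOINTS[-1]]))
  B <- rlnorm_mean_cv(n, cfg$baseline_ci_mean,
                      cfg$baseline_ci_sd / cfg$baseline_ci_mean)
  ref <- test <- matrix(0, n, 4)
  for (k in 1:4) {
    L <- B * m[k]
    B2 <- rlnorm_mean_cv(n, cfg$baseline_ci_mean,
                         cfg$baseline_ci_sd / cfg$baseline_ci_mean)
    signal <- pmax(0.05, cfg$test_scale *
                     (cfg$fidelity * L + (1 - cfg$fidelity) * B2 * m[k]) +
                     cfg$test_bias)
    ref[, k] <- L * (lnoise(n, cfg$ref_noise_cv) +
                       lnoise(n, cfg$ref_noise_cv)) / 2
    test[, k] <- signal * (lnoise(n, cfg$test_noise_cv) +
                             lnoise(n, cfg$test_noise_cv)) / 2
  }
  d_ref <- as.vector(ref[, 2:4] - ref[, 1:3])
  d_test <- as.vector(test[, 2:4] - test[, 1:3])
  s_mean <- (d_ref + d_test) / 2
  neg <- s_mean < 0
  d_ref[neg] <- -d_ref[neg]
  d_test[neg] <- -d_test[neg]
  radius <- abs(s_mean)
  angle <- atan2(d_test, d_ref) * 180 / pi - 45
  angle[angle <= -90] <- angle[angle <= -90] + 180
  angle[radius == 0] <- 0
  keep <- radius >= 0.10 * mean_ref
  if (!any(keep)) return(list(concordance = NA_real_, mean_angle = NA_real_))
  list(
    concordance = 100 * mean(abs(angle[keep]) <= 30),
    mean_angle = mean(angle[keep])
  )
}
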