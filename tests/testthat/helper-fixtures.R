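# In-code fixtures: small record and pair tables built programmatically.

# One measurement row with sensible defaults for the unspecified fields.
make_record <- function(subject_id = "S1", timepoint = "baseline",
                        method = "reference", replicate_index = 1L,
                        ci = 4.5, svi = 30, svri = 1400, svv = 15,
                        hr = 150, sbp = 90, dpdt = NA_real_) {
  tibble::tibble(
    subject_id = subject_id, timepoint = timepoint, method = method,
    replicate_index = as.integer(replicate_index),
    ci = ci, svi = svi, svri = svri, svv = svv, hr = hr, sbp = sbp,
    dpdt = dpdt
  )
}

# A replicate series for one (subject, timepoint, method), varying only ci.
make_series <- function(ci, method = "reference", subject_id = "S1",
                        timepoint = "baseline", ...) {
  make_record(subject_id = subject_id, timepoint = timepoint,
              method = method, replicate_index = seq_along(ci), ci = ci, ...)
}

# A minimal QC-passed pairs table for one variable.
make_pairs <- function(ref, test, variable = "ci",
                       subject_id = paste0("P", seq_along(ref)),
                       timepoint = "baseline") {
  out <- tibble::tibble(
    subject_id = subject_id,
    timepoint = factor(timepoint, levels = c("baseline", "rosc15",
                                             "rosc30", "rosc60")),
    qc_pass = TRUE
  )
  out[[paste0(variable, "_ref")]] <- ref
  out[[paste0(variable, "_test")]] <- test
  out
}

# Paired reference/test records (one replicate each) for pair_and_filter.
make_paired_records <- function(subject_id = "S1", timepoint = "baseline",
                                sbp_ref = 90, sbp_test = 90,
                                dpdt = 1.0, ci = 4.5, ...) {
  dplyr::bind_rows(
    make_record(subject_id, timepoint, "reference", 1L, ci = ci,
                sbp = sbp_ref, ...),
    make_record(subject_id, timepoint, "test", 1L, ci = ci,
                sbp = sbp_test, dpdt = dpdt, ...)
  )
}
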