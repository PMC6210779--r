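#' Per-subject mean error rate between estimated and reference values
#'
#' For each subject, the percentage deviation of the accelerometer estimate
#' from the reference value: `100 * |estimated - reference| / reference`
#' (absolute by default; reported concurrent-validity errors are
#' conventionally all-positive). The signed variant is available via
#' `signed = TRUE`. The summary mean is the arithmetic mean over subjects
#' and the spread is the sample (n - 1) standard deviation.
#'
#' @param estimated,reference Numeric per-subject values of equal length;
#'   no reference value may be 0.
#' @param signed Return signed percentage errors instead of absolute ones.
#' @return A list with `per_subject` (% errors), `mean` (%), `sd` (%).
#' @export
mean_error_rate <- function(estimated, reference, signed = FALSE) {
  if (length(estimated) != length(reference)) {
    abort("pairing error: estimated and reference lengths differ.")
  }
  zero <- which(reference == 0)
  if (length(zero) > 0) {
    abort(paste0("division error: reference value 0 for subject(s) ",
                 paste(zero, collapse = ", ")))
  }
  err <- 100 * (estimated - reference) / reference
  if (!signed) err <- abs(err)
  list(
    per_subject = err,
    mean = mean(err),
    sd = if (length(err) > 1) sd(err) else NA_real_
  )
}

#' Pearson correlation between paired per-subject values
#'
#' Product-moment correlation; both inputs must be non-constant and of
#' equal length at least 3.
#'
#' @param x,y Numeric vectors.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("pairing error: lengths differ.")
  if (length(x) < 3) abort("need at least 3 paired values.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("undefined correlation: constant input.")
  }
  cor(x, y)
}

#' Concurrent-validity report for the five gait parameters
#'
#' Joins an estimated and a reference per-subject table by `subject_id` and
#' computes, for each gait parameter, the per-subject mean error rate and
#' the Pearson correlation between the two systems.
#'
#' @param estimated,reference Data frames with a `subject_id` column and the
#'   five parameter columns `avg_step_time`, `avg_stride_time`,
#'   `avg_step_length`, `avg_stride_length`, `walking_speed`. Both tables
#'   must cover the same subjects.
#' @param parameters Parameter columns to validate.
#' @param signed Passed to [mean_error_rate()].
#' @return A list of class `fog_validation` with `results` (one row per
#'   parameter: `parameter`, `mean_error`, `sd_error`, `pearson_r`,
#'   `n_subjects`) and `per_subject` (long tibble of per-subject errors).
#' @export
validation_report <- function(estimated, reference,
                              parameters = c("avg_step_time",
                                             "avg_stride_time",
                                             "avg_step_length",
                                             "avg_stride_length",
                                             "walking_speed"),
                              signed = FALSE) {
  est <- as_tibble(estimated)
  ref <- as_tibble(reference)
  if (!"subject_id" %in% names(est) || !"subject_id" %in% names(ref)) {
    abort("both tables need a `subject_id` column.")
  }
  only_est <- setdiff(est$subject_id, ref$subject_id)
  only_ref <- setdiff(ref$subject_id, est$subject_id)
  if (length(only_est) > 0 || length(only_ref) > 0) {
    abort(paste0("join error: subjects present in one table only: ",
                 paste(c(only_est, only_ref), collapse = ", ")))
  }
  missing_cols <- setdiff(parameters, intersect(names(est), names(ref)))
  if (length(missing_cols) > 0) {
    abort(paste0("missing parameter column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  joined <- dplyr::inner_join(est[c("subject_id", parameters)],
                              ref[c("subject_id", parameters)],
                              by = "subject_id", suffix = c("_est", "_ref"))
  per_subject <- purrr::map_dfr(parameters, function(p) {
    mer <- mean_error_rate(joined[[paste0(p, "_est")]],
                           joined[[paste0(p, "_ref")]], signed = signed)
    tibble(parameter = p, subject_id = joined$subject_id,
           estimated = joined[[paste0(p, "_est")]],
           reference = joined[[paste0(p, "_ref")]],
           error_pct = mer$per_subject)
  })
  results <- purrr::map_dfr(parameters, function(p) {
    mer <- mean_error_rate(joined[[paste0(p, "_est")]],
                           joined[[paste0(p, "_ref")]], signed = signed)
    tibble(
      parameter = p,
      mean_error = mer$mean,
      sd_error = mer$sd,
      pearson_r = pearson_correlation(joined[[paste0(p, "_est")]],
                                      joined[[paste0(p, "_ref")]]),
      n_subjects = nrow(joined)
    )
  })
  structure(list(results = results, per_subject = per_subject),
            class = "fog_validation")
}

#' @export
print.fog_validation <- function(x, ...) {
  cat("Concurrent-validity report (", x$results$n_subjects[1],
      " subjects)\n", sep = "")
  print(as.data.frame(x$results), row.names = FALSE, digits = 4)
  invisible(x)
}
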