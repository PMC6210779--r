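#' Tidy a concurrent-validity report
#'
#' @param x A `fog_validation` from [validation_report()].
#' @param ... Unused.
#' @return One row per parameter: `parameter`, `mean_error`, `sd_error`,
#'   `pearson_r`, `n_subjects`.
#' @export
tidy.fog_validation <- function(x, ...) x$results

#' @rdname tidy.fog_validation
#' @export
glance.fog_validation <- function(x, ...) {
  tibble(
    n_parameters = nrow(x$results),
    n_subjects = x$results$n_subjects[1],
    max_mean_error = max(x$results$mean_error),
    min_pearson_r = min(x$results$pearson_r)
  )
}

#' Tidy a classification report
#'
#' @param x A `fog_report` from [run_simulations()] or
#'   [classification_report()].
#' @param ... Unused.
#' @return Per-simulation metrics in long-friendly wide form.
#' @export
tidy.fog_report <- function(x, ...) {
  dplyr::mutate(x$per_simulation, classifier_kind = x$classifier_kind,
                .before = 1)
}

#' @rdname tidy.fog_report
#' @export
glance.fog_report <- function(x, ...) {
  tibble(
    classifier_kind = x$classifier_kind,
    n_simulations = nrow(x$per_simulation),
    mean_accuracy = x$mean_accuracy,
    mean_sensitivity = x$mean_sensitivity,
    mean_specificity = x$mean_specificity
  )
}

#' Tidy a set of classification reports
#'
#' @param x A `fog_report_set` from [run_simulations()].
#' @param ... Unused.
#' @return Row-bound per-simulation metrics of all classifiers.
#' @export
tidy.fog_report_set <- function(x, ...) purrr::map_dfr(x, tidy)

#' @rdname tidy.fog_report_set
#' @export
glance.fog_report_set <- function(x, ...) purrr::map_dfr(x, glance)

#' Tidy an augmented feature matrix
#'
#' @param x A `fog_augmented` from [pca_augment()].
#' @param ... Unused.
#' @return The component loadings in long form: `component`, `feature`,
#'   `loading`.
#' @export
tidy.fog_augmented <- function(x, ...) {
  rot <- attr(x, "transform")$rotation
  tibble(
    component = rep(colnames(rot) %||% paste0("PC", seq_len(ncol(rot))),
                    each = nrow(rot)),
    feature = rep(rownames(rot), times = ncol(rot)),
    loading = as.numeric(rot)
  )
}

#' @rdname tidy.fog_augmented
#' @export
glance.fog_augmented <- function(x, ...) {
  ev <- attr(x, "explained_variance")
  tibble(
    n_components = length(ev),
    n_columns = sum(grepl("^pc[0-9]+$", names(x))) +
      sum(names(x) %in% feature_names),
    total_explained_variance = sum(ev)
  )
}

#' Tidy a gait summary
#'
#' @param x A `gait_summary` from [summarize_gait()].
#' @param ... Unused.
#' @return The per-step records.
#' @export
tidy.gait_summary <- function(x, ...) x$steps

#' @rdname tidy.gait_summary
#' @export
glance.gait_summary <- function(x, ...) x$summary
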