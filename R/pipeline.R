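#' Process one recording end to end
#'
#' Realign to horizontal-vertical coordinates, low-pass filter, detect
#' initial contacts and summarise the five gait parameters.
#'
#' @param rec An [accel_recording].
#' @param config A [pipeline_config()] (or a named list of overrides).
#' @return A list with `aligned`, `ics`, `gait` (a `gait_summary`) and
#'   `summary` (its one-row tibble).
#' @export
process_recording <- function(rec, config = pipeline_config()) {
  cfg <- pipeline_config_resolve(config)
  aligned <- realign_to_horizontal_vertical(rec)
  aligned <- lowpass_filter(aligned, order = cfg$filter$order,
                            cutoff = cfg$filter$cutoff_hz)
  ics <- find_initial_contacts(
    aligned, scale = cfg$cwt$scale,
    prominence_frac = cfg$detect$prominence_frac,
    min_separation_s = cfg$detect$min_separation_s,
    filter_first = FALSE
  )
  gait <- summarize_gait(
    ics, aligned$vertical, sampling_rate(aligned),
    config = pendulum_config(Wp = cfg$pendulum$Wp_m, KG = cfg$pendulum$KG),
    ic_guard = cfg$detect$ic_guard
  )
  list(aligned = aligned, ics = ics, gait = gait, summary = gait$summary)
}

#' Pipeline configuration
#'
#' Central container for every tunable of the pipeline, with the package
#' defaults: 32 Hz sampling, 0.34 m sensor height, 4th-order 15 Hz
#' zero-phase Butterworth filter, cadence-adaptive smoothing scale,
#' prominence fraction 0.5, 0.25 s minimum contact separation, single-sample
#' IC despiking before double integration, pendulum constants Wp = 0.34 m / KG = 4,
#' 20 harmonics, and the 70:30 x 10-simulation classification protocol.
#' Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults, nested as in the return
#'   value, e.g. `pipeline_config(filter = list(cutoff_hz = 10))`.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    sampling_rate = 32,
    sensor_height = 0.34,
    seed = 1,
    filter = list(order = 4, cutoff_hz = 15),
    cwt = list(scale = "auto"),
    detect = list(prominence_frac = 0.5, min_separation_s = 0.25,
                  ic_guard = 0),
    pendulum = list(Wp_m = 0.34, KG = 4),
    features = list(n_harmonics = 20),
    classify = list(train_fraction = 0.7, n_simulations = 10,
                    kinds = c("svm_rbf", "knn", "dt", "nb"))
  )
  overrides <- list(...)
  for (key in names(overrides)) {
    if (!key %in% names(cfg)) abort(paste0("unknown config key: ", key))
    if (is.list(cfg[[key]]) && is.list(overrides[[key]])) {
      sub <- overrides[[key]]
      bad <- setdiff(names(sub), names(cfg[[key]]))
      if (length(bad) > 0) {
        abort(paste0("unknown config key: ", key, ".", bad[1]))
      }
      cfg[[key]][names(sub)] <- sub
    } else {
      cfg[[key]] <- overrides[[key]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

pipeline_config_resolve <- function(config) {
  if (inherits(config, "pipeline_config")) return(config)
  do.call(pipeline_config, as.list(config))
}

#' Simulate a full labelled study cohort
#'
#' Generates one synthetic walk per subject for a two-class cohort. FoG
#' subjects walk with longer, more variable step times and smaller vertical
#' excursions than noFoG subjects (per-subject means drawn around
#' class-level values), giving the classes a realistic, overlapping
#' separation in the derived gait features. Optionally writes each
#' recording to `dir` as a delimited file.
#'
#' @param n_fog,n_nofog Class sizes (defaults 36 and 15).
#' @param seed Integer base seed; subject `i` uses `seed * 1000 + i` for its
#'   walk.
#' @param n_steps Steps per recording (default 30).
#' @param dir Optional directory for per-subject CSV files.
#' @param noise_sd Sensor noise in g (default 0.02).
#' @return A list of class `fog_study`: `walks` (named list of `fog_walk`),
#'   `truth` (per-subject reference table of the five parameters),
#'   `metadata` (subject_id, label).
#' @export
simulate_study <- function(n_fog = 36, n_nofog = 15, seed = 1, n_steps = 30,
                           dir = NULL, noise_sd = 0.02) {
  n <- n_fog + n_nofog
  labels <- c(rep("FoG", n_fog), rep("noFoG", n_nofog))
  ids <- sprintf("S%02d", seq_len(n))
  set.seed(seed)
  # per-subject true walking characteristics; FoG slower, shorter excursion
  st_mean <- ifelse(labels == "FoG", rnorm(n, 0.60, 0.03), rnorm(n, 0.52, 0.03))
  d_mean <- ifelse(labels == "FoG", rnorm(n, 0.004, 0.0008),
                   rnorm(n, 0.006, 0.0008))
  st_mean <- pmax(st_mean, 0.40)
  d_mean <- pmax(d_mean, 0.0015)
  walks <- purrr::map(seq_len(n), function(i) {
    simulate_walk(
      n_steps = n_steps, step_time_mean = st_mean[i], step_time_sd = 0.02,
      D_mean = d_mean[i], D_sd = 0.0005, noise_sd = noise_sd,
      subject_id = ids[i], label = labels[i],
      seed = (seed * 1000 + i) %% .Machine$integer.max
    )
  })
  names(walks) <- ids
  truth <- purrr::map_dfr(walks, function(w) w$truth$summary)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(n)) {
      write_recording(walks[[i]]$recording,
                      file.path(dir, paste0(ids[i], "_left.csv")))
    }
  }
  structure(
    list(walks = walks, truth = truth,
         metadata = tibble(subject_id = ids, label = labels)),
    class = "fog_study"
  )
}

#' Run the validation endpoint of the pipeline
#'
#' For every subject: realign, filter, detect initial contacts, estimate
#' the five gait parameters; then compare the per-subject estimates with a
#' reference table via [validation_report()]. Subjects failing any stage
#' are skipped with a warning; the pipeline fails only when all subjects
#' fail.
#'
#' @param recordings A named list of [accel_recording] objects, a
#'   `fog_study`, or a directory of delimited recording files.
#' @param reference Reference table (`subject_id` + the five parameter
#'   columns); for a `fog_study` it defaults to the generator truth.
#' @param config A [pipeline_config()].
#' @return A list of class `fog_validation_run`: `estimates` (per-subject
#'   tibble), `report` (a `fog_validation`), `skipped` (character).
#' @export
run_validation_pipeline <- function(recordings, reference = NULL,
                                    config = pipeline_config()) {
  cfg <- pipeline_config_resolve(config)
  if (inherits(recordings, "fog_study")) {
    if (is.null(reference)) reference <- recordings$truth
    recordings <- purrr::map(recordings$walks, "recording")
  } else if (is.character(recordings) && length(recordings) == 1) {
    files <- list.files(recordings, pattern = "\\.(csv|tsv|txt)$",
                        full.names = TRUE)
    files <- files[!grepl("^(reference_truth|subjects)\\.", basename(files))]
    if (length(files) == 0) abort("no recording files found in directory.")
    # files named <subject>_<side>.<ext> carry their side; otherwise left
    recordings <- purrr::map(files, function(f) {
      stem <- sub("\\.[^.]*$", "", basename(f))
      side <- if (grepl("_(left|right)$", stem)) sub("^.*_", "", stem)
              else "left"
      read_recording(f, sampling_rate = cfg$sampling_rate,
                     sensor_height = cfg$sensor_height, side = side,
                     subject_id = sub("_(left|right)$", "", stem))
    })
    names(recordings) <- purrr::map_chr(recordings, attr, "subject_id")
  }
  if (is.null(reference)) abort("a reference table is required.")
  skipped <- character()
  estimates <- purrr::map_dfr(recordings, function(rec) {
    res <- tryCatch(process_recording(rec, cfg), error = function(e) {
      warn(paste0("subject '", attr(rec, "subject_id"), "' skipped: ",
                  conditionMessage(e)))
      NULL
    })
    if (is.null(res)) {
      skipped <<- c(skipped, attr(rec, "subject_id"))
      return(NULL)
    }
    res$summary
  })
  if (nrow(estimates) == 0) abort("all subjects failed processing.")
  report <- validation_report(estimates, reference)
  structure(list(estimates = estimates, report = report, skipped = skipped),
            class = "fog_validation_run")
}

#' Run the classification endpoint of the pipeline
#'
#' Assembles the 14-feature vector per subject (when given recordings) and
#' runs the repeated stratified-split protocol over the four classifiers,
#' with the PCA augmentation fitted inside each simulation's training fold.
#'
#' @param x A per-subject feature table with a `label` column (e.g. from
#'   [simulate_feature_cohort()]), or a `fog_study` whose recordings are
#'   processed and featurised first.
#' @param config A [pipeline_config()].
#' @param base_seed Base seed for the simulations (default `config$seed`).
#' @return A `fog_report_set` (named list of `fog_report`, one per
#'   classifier).
#' @export
run_classification_pipeline <- function(x, config = pipeline_config(),
                                        base_seed = NULL) {
  cfg <- pipeline_config_resolve(config)
  base_seed <- base_seed %||% cfg$seed
  features <- if (inherits(x, "fog_study")) {
    extract_study_features(x, cfg)
  } else {
    as_tibble(x)
  }
  if (!"label" %in% names(features)) {
    abort("missing labels: the feature table needs a `label` column.")
  }
  run_simulations(
    features, features$label,
    kinds = cfg$classify$kinds,
    n_simulations = cfg$classify$n_simulations,
    base_seed = base_seed,
    train_fraction = cfg$classify$train_fraction
  )
}

#' Extract the per-subject 14-feature table from a study
#'
#' @param study A `fog_study`.
#' @param config A [pipeline_config()].
#' @return A tibble with `subject_id`, `label` and the 14 feature columns.
#' @export
extract_study_features <- function(study, config = pipeline_config()) {
  cfg <- pipeline_config_resolve(config)
  purrr::map_dfr(study$walks, function(w) {
    res <- process_recording(w$recording, cfg)
    assemble_features(res$gait, w$recording, res$ics,
                      n_harmonics = cfg$features$n_harmonics)
  })
}
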