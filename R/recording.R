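#' Construct an accelerometer recording
#'
#' An accelerometer recording is a tibble with columns `time`, `ax`, `ay`,
#' `az` (acceleration in g) plus metadata attributes: sampling rate, sensor
#' height above ground, body side, subject id and FoG label. Sample `i` has
#' timestamp `(i - 1) / sampling_rate`; the time base is always uniform.
#'
#' @param ax,ay,az Numeric vectors of equal length, acceleration in g.
#' @param sampling_rate Sampling frequency in Hz (default 32).
#' @param sensor_height Sensor height above ground in metres (default 0.34,
#'   a knee-worn placement).
#' @param side `"left"` or `"right"`.
#' @param subject_id Subject identifier.
#' @param label `"FoG"`, `"noFoG"` or `"unknown"`.
#' @param sensor_sourced If `TRUE` the samples are checked against the
#'   +/-8 g range of the target sensor.
#' @return A tibble of class `accel_recording`.
#' @export
accel_recording <- function(ax, ay, az, sampling_rate = 32,
                            sensor_height = 0.34,
                            side = c("left", "right"),
                            subject_id = "subject",
                            label = c("unknown", "FoG", "noFoG"),
                            sensor_sourced = FALSE) {
  side <- match.arg(side)
  label <- match.arg(label)
  n <- length(ax)
  if (length(ay) != n || length(az) != n) {
    abort("`ax`, `ay` and `az` must have equal length.")
  }
  if (n < 2) abort("a recording needs at least 2 samples.")
  if (!all(is.finite(ax)) || !all(is.finite(ay)) || !all(is.finite(az))) {
    abort("all sample values must be finite.")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0) {
    abort("`sampling_rate` must be a single positive number.")
  }
  if (sensor_height <= 0) abort("`sensor_height` must be positive.")
  if (sensor_sourced &&
      any(abs(c(ax, ay, az)) > 8)) {
    abort("sensor-sourced samples must lie within [-8, 8] g.")
  }
  out <- tibble(
    time = (seq_len(n) - 1) / sampling_rate,
    ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az)
  )
  structure(
    out,
    class = c("accel_recording", class(out)),
    sampling_rate = sampling_rate,
    sensor_height = sensor_height,
    side = side,
    subject_id = subject_id,
    label = label,
    sensor_sourced = sensor_sourced
  )
}

#' Sampling rate of a recording or derived signal
#' @param x An object carrying a `sampling_rate` attribute.
#' @return Sampling frequency in Hz.
#' @export
sampling_rate <- function(x) attr(x, "sampling_rate")

#' Read a triaxial accelerometer file
#'
#' Reads a delimited text file (comma or tab separated, header row) with
#' columns `ax`, `ay`, `az` and an optional `time` column, all in g. A time
#' column, when present, is validated for uniform spacing (tolerance 10% of
#' the sample period) and then discarded: timestamps are rebuilt from
#' `sampling_rate` so that downstream indexing is exact.
#'
#' @param path Path to the file.
#' @inheritParams accel_recording
#' @return A tibble of class [accel_recording].
#' @export
read_recording <- function(path, sampling_rate = 32, sensor_height = 0.34,
                           side = c("left", "right"),
                           subject_id = NULL, label = "unknown",
                           sensor_sourced = FALSE) {
  side <- match.arg(side)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- utils::read.table(path, header = TRUE, sep = "",
                           colClasses = "character",
                           strip.white = TRUE, check.names = FALSE)
  if (ncol(raw) == 1) { # comma-delimited
    raw <- utils::read.csv(path, header = TRUE, colClasses = "character",
                           strip.white = TRUE, check.names = FALSE)
  }
  names(raw) <- tolower(trimws(names(raw)))
  need <- c("ax", "ay", "az")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("format error: missing axis column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) < 2) abort("input error: fewer than 2 data rows.")
  num <- lapply(raw[c(need, intersect("time", names(raw)))], function(col) {
    suppressWarnings(as.numeric(col))
  })
  for (nm in names(num)) {
    bad <- which(is.na(num[[nm]]) & !(trimws(raw[[nm]]) %in% c("NA", "")))
    bad <- union(bad, which(is.na(num[[nm]])))
    if (length(bad) > 0) {
      abort(paste0("parse error: non-numeric value in column '", nm,
                   "' at data row ", bad[1]))
    }
  }
  if (!is.null(num$time)) {
    dt <- diff(num$time)
    if (any(abs(dt - 1 / sampling_rate) > 0.1 / sampling_rate)) {
      abort("time column is not uniformly spaced at `sampling_rate` (10% tolerance).")
    }
  }
  accel_recording(num$ax, num$ay, num$az,
                  sampling_rate = sampling_rate,
                  sensor_height = sensor_height, side = side,
                  subject_id = subject_id,
                  label = match.arg(label, c("unknown", "FoG", "noFoG")),
                  sensor_sourced = sensor_sourced)
}

#' Write a recording or aligned signal to delimited text
#'
#' @param x An [accel_recording] or the result of
#'   [realign_to_horizontal_vertical()].
#' @param path Output file path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_recording <- function(x, path, delim = ",") {
  readr::write_delim(as_tibble(as.data.frame(x)), path, delim = delim)
  invisible(path)
}

#' Realign a recording to horizontal-vertical coordinates
#'
#' Sensor tilt is estimated from the recording-mean acceleration vector,
#' which for a (quasi-)static wear period points along gravity. Two
#' successive rotations (about the sensor y then x axis) bring that mean
#' vector onto the vertical axis; 1 g is then subtracted from the rotated
#' vertical component. The rotation is orthonormal, so per-sample vector
#' norms are preserved exactly, and it is stored in the result so it can be
#' inverted with [unrealign()].
#'
#' Exactly 1 g is removed (not the mean-vector norm): walking dynamics give
#' the recording mean a genuine non-zero vertical component, and absorbing
#' it into the gravity estimate would bias the per-step double integration
#' used for step length. Consequently the returned vertical has exactly zero
#' mean only for quasi-static recordings.
#'
#' @param rec An [accel_recording] of duration >= 2 s.
#' @return A tibble of class `accel_aligned` with columns `time`,
#'   `vertical`, `ap`, `ml` (g; gravity removed from `vertical`).
#' @export
realign_to_horizontal_vertical <- function(rec) {
  stopifnot(inherits(rec, "accel_recording"))
  fs <- sampling_rate(rec)
  if (nrow(rec) / fs < 2) {
    abort("recording must be at least 2 s long to estimate orientation.")
  }
  m <- c(mean(rec$ax), mean(rec$ay), mean(rec$az))
  nm <- sqrt(sum(m^2))
  if (nm < 0.5 || nm > 1.5) {
    abort(paste0("orientation-estimation error: mean acceleration norm ",
                 signif(nm, 4), " g is not a plausible gravity reference."))
  }
  rot <- .gravity_rotation(m)
  xyz <- rbind(rec$ax, rec$ay, rec$az)
  r <- rot %*% xyz
  out <- tibble(
    time = rec$time,
    vertical = r[3, ] - 1,
    ap = r[1, ],
    ml = r[2, ]
  )
  structure(
    out,
    class = c("accel_aligned", class(out)),
    sampling_rate = fs,
    source_id = attr(rec, "subject_id"),
    side = attr(rec, "side"),
    sensor_height = attr(rec, "sensor_height"),
    label = attr(rec, "label"),
    rotation = rot
  )
}

# Rotation matrix aligning vector m with the +z axis: first about y (removes
# the x component), then about x (removes the y component).
.gravity_rotation <- function(m) {
  h <- sqrt(m[1]^2 + m[3]^2)
  ca <- if (h > 0) m[3] / h else 1
  sa <- if (h > 0) m[1] / h else 0
  r1 <- matrix(c(ca, 0, -sa,
                 0, 1, 0,
                 sa, 0, ca), 3, 3, byrow = TRUE)
  g0 <- sqrt(m[2]^2 + h^2)
  cb <- h / g0
  sb <- m[2] / g0
  r2 <- matrix(c(1, 0, 0,
                 0, cb, -sb,
                 0, sb, cb), 3, 3, byrow = TRUE)
  r2 %*% r1
}

#' Invert a realignment
#'
#' Restores the raw sensor-frame signal from an aligned one: adds gravity
#' back to the vertical component and applies the stored rotation's
#' transpose.
#'
#' @param aligned Result of [realign_to_horizontal_vertical()].
#' @return A tibble with columns `time`, `ax`, `ay`, `az`.
#' @export
unrealign <- function(aligned) {
  stopifnot(inherits(aligned, "accel_aligned"))
  rot <- attr(aligned, "rotation")
  v <- rbind(aligned$ap, aligned$ml, aligned$vertical + 1)
  xyz <- t(rot) %*% v
  tibble(time = aligned$time, ax = xyz[1, ], ay = xyz[2, ], az = xyz[3, ])
}

#' Zero-phase Butterworth low-pass filter
#'
#' Fourth-order Butterworth by default, applied forward and backward
#' (`signal::filtfilt`) so that event timing is not shifted; DC gain is 1.
#' At the 32 Hz sensor rate the 15 Hz default cutoff is valid but close to
#' the Nyquist frequency, which triggers a warning rather than an error.
#'
#' @param x Numeric vector (uniformly sampled series) or an `accel_aligned`
#'   tibble, in which case `vertical`, `ap` and `ml` are each filtered.
#' @param sampling_rate Sampling frequency in Hz (taken from `x` when it is
#'   an aligned signal).
#' @param order Filter order (default 4).
#' @param cutoff Cutoff frequency in Hz (default 15).
#' @return Filtered series of the same length / shape as the input.
#' @export
lowpass_filter <- function(x, sampling_rate = NULL, order = 4, cutoff = 15) {
  if (inherits(x, "accel_aligned")) {
    fs <- sampling_rate %||% sampling_rate(x)
    for (col in c("vertical", "ap", "ml")) {
      x[[col]] <- lowpass_filter(x[[col]], fs, order = order, cutoff = cutoff)
    }
    return(x)
  }
  fs <- sampling_rate
  if (is.null(fs)) abort("`sampling_rate` is required for a bare series.")
  if (order < 1) abort("`order` must be >= 1.")
  nyq <- fs / 2
  if (cutoff <= 0 || cutoff >= nyq) {
    abort(paste0("parameter error: cutoff must lie in (0, ", nyq, ") Hz."))
  }
  if (cutoff >= 0.9 * nyq) {
    warn(paste0("cutoff ", cutoff, " Hz is within 10% of the Nyquist ",
                "frequency (", nyq, " Hz); attenuation will be minimal."))
  }
  if (length(x) <= 3 * order) {
    abort("series too short for the requested filter order.")
  }
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  .filtfilt_padded(bf, x, padlen = 3 * (2 * order + 1))
}

# Zero-phase filtering with odd-reflection padding and offset-corrected
# initial conditions, so that constants pass exactly and edge transients do
# not leak into the series (plain forward-backward filtering from zero
# state distorts the first and last samples).
.filtfilt_padded <- function(bf, x, padlen) {
  n <- length(x)
  p <- min(padlen, n - 1)
  xx <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  one_pass <- function(z) {
    as.numeric(signal::filter(bf, z - z[1])) + z[1]
  }
  y <- rev(one_pass(xx))
  y <- rev(one_pass(y))
  y[(p + 1):(p + n)]
}
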