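#' Inverted-pendulum configuration
#'
#' Holds the two constants of the extended inverted-pendulum model: the
#' sensor height above ground `Wp` (metres, default 0.34 for a knee-worn
#' sensor) and the dimensionless multiplying factor `KG` (default 4) that
#' maps the sensor position to the body's centre of mass. A generic `KG`
#' avoids per-subject calibration.
#'
#' @param Wp Sensor height above ground in metres (> 0).
#' @param KG Multiplying factor (> 0).
#' @return A list of class `pendulum_config`.
#' @export
pendulum_config <- function(Wp = 0.34, KG = 4) {
  if (!is.numeric(Wp) || Wp <= 0) abort("`Wp` must be positive.")
  if (!is.numeric(KG) || KG <= 0) abort("`KG` must be positive.")
  structure(list(Wp = Wp, KG = KG), class = "pendulum_config")
}

#' Step times from an initial-contact series
#'
#' `step_time(i) = IC(i + 1) - IC(i)`: successive initial contacts belong to
#' opposite feet, so each interval is one step.
#'
#' @param ics A `gait_ics` tibble or a numeric vector of IC times (s).
#' @return Numeric vector of length `n - 1` (empty when fewer than 2 ICs).
#' @export
step_times <- function(ics) {
  t <- .ic_times(ics)
  if (length(t) < 2) return(numeric())
  diff(t)
}

#' Stride times from an initial-contact series
#'
#' `stride_time(i) = IC(i + 2) - IC(i)`: a stride spans two steps, returning
#' to the same foot, so `stride_time(i) = step_time(i) + step_time(i + 1)`
#' exactly.
#'
#' @inheritParams step_times
#' @return Numeric vector of length `n - 2` (empty when fewer than 3 ICs).
#' @export
stride_times <- function(ics) {
  t <- .ic_times(ics)
  if (length(t) < 3) return(numeric())
  t[-(1:2)] - t[seq_len(length(t) - 2)]
}

.ic_times <- function(ics) {
  t <- if (is.data.frame(ics)) ics$ic_time else as.numeric(ics)
  if (is.unsorted(t, strictly = TRUE)) {
    abort("initial-contact times must be strictly increasing.")
  }
  t
}

#' Vertical excursion of the sensor over one step
#'
#' Double-integrates the gravity-free vertical acceleration of a single step
#' (one IC to the next) to displacement and returns its peak-to-trough range
#' `D` in metres. Acceleration is converted from g to m/s^2 at this single
#' point of use.
#'
#' Two drift-correction rules are available:
#' \describe{
#'   \item{`"velocity_mean"` (default)}{subtract the mean of the integrated
#'     velocity (the unknown integration constant), then integrate again.
#'     This preserves a low-high-low pendulum arc spanning the step — the
#'     waveform the model assumes — exactly, and recovers `D = 2A` for a
#'     full-period sinusoid. (A linear detrend of the displacement would
#'     re-bias both: a sine has a non-zero linear component over a single
#'     period, so detrending it removes genuine excursion.)}
#'   \item{`"velocity_linear"`}{remove the full linear trend of the velocity
#'     before the second integration, then linearly detrend the
#'     displacement. This annihilates the quadratic displacement growth
#'     caused by a constant acceleration bias, but also removes most of a
#'     genuine half-period arc, so it is only appropriate when the vertical
#'     zero level is untrusted.}
#' }
#' The two goals (keep the arc, kill a constant bias) cannot both be met by
#' one per-step rule: over a single step a constant bias produces exactly
#' the symmetric parabola an arc produces. The pipeline therefore anchors
#' the vertical zero level absolutely (see
#' [realign_to_horizontal_vertical()]) and uses the default rule.
#'
#' @param segment Vertical acceleration (g, gravity removed) spanning one
#'   step, at least 4 samples.
#' @param sampling_rate Sampling frequency in Hz.
#' @param drift Drift-correction rule, see Details.
#' @return Excursion `D` in metres (>= 0).
#' @export
vertical_excursion <- function(segment, sampling_rate,
                               drift = c("velocity_mean", "velocity_linear")) {
  drift <- match.arg(drift)
  if (length(segment) < 4) abort("input error: segment shorter than 4 samples.")
  if (!all(is.finite(segment))) abort("input error: non-finite segment values.")
  a <- segment * GRAVITY_MS2
  v <- as.numeric(pracma::cumtrapz(a)) / sampling_rate
  v <- if (drift == "velocity_mean") v - mean(v)
       else as.numeric(pracma::detrend(v, tt = "linear"))
  y <- as.numeric(pracma::cumtrapz(v)) / sampling_rate
  if (drift == "velocity_linear") {
    y <- as.numeric(pracma::detrend(y, tt = "linear"))
  }
  max(y) - min(y)
}

#' Step length from the inverted-pendulum model
#'
#' `step_length = KG * 2 * sqrt(2 * Wp * D - D^2)`: the chord length swept
#' by an inverted pendulum of height `Wp` whose apex drops by `D`, scaled by
#' the generic factor `KG`.
#'
#' @param D Vertical excursion in metres, `0 <= D <= 2 * Wp` (vectorised).
#' @param config A [pendulum_config()].
#' @return Step length in metres.
#' @export
step_length <- function(D, config = pendulum_config()) {
  if (any(D < 0 | D > 2 * config$Wp)) {
    abort("domain error: D must lie in [0, 2 * Wp] (negative radicand).")
  }
  config$KG * 2 * sqrt(pmax(2 * config$Wp * D - D^2, 0))
}

#' Stride length
#'
#' Exactly twice the step length.
#'
#' @param step_length Step length in metres (>= 0, vectorised).
#' @return Stride length in metres.
#' @export
stride_length <- function(step_length) {
  if (any(step_length < 0)) abort("domain error: negative step length.")
  2 * step_length
}

#' Walking speed
#'
#' Mean step length over mean step time.
#'
#' @param avg_step_length Average step length in metres.
#' @param avg_step_time Average step time in seconds (> 0).
#' @return Speed in m/s.
#' @export
walking_speed <- function(avg_step_length, avg_step_time) {
  if (any(avg_step_time <= 0)) abort("domain error: average step time must be > 0.")
  avg_step_length / avg_step_time
}

#' Interpolate the vertical signal across initial-contact transients
#'
#' The heel-strike transient is an impact artifact, not centre-of-mass
#' motion; because linear filtering preserves its impulse (area), it would
#' otherwise inject a spurious velocity step into every integrated segment.
#' Samples within `guard` samples of each IC (just the IC sample itself by
#' default) are replaced by linear interpolation between the surrounding
#' clean samples. Wider windows start eating into the genuine pendulum arc,
#' so the default is deliberately minimal.
#'
#' @param vertical Vertical acceleration series (g).
#' @param ic_indices Integer sample indices of the detected ICs.
#' @param guard Half-width of the exclusion window in samples (default 0:
#'   only the IC sample is replaced).
#' @return The despiked series.
#' @export
despike_at_ics <- function(vertical, ic_indices, guard = 0) {
  n <- length(vertical)
  drop <- unique(unlist(lapply(ic_indices, function(i) {
    seq(max(1, i - guard), min(n, i + guard))
  })))
  keep <- setdiff(seq_len(n), drop)
  if (length(keep) < 2) abort("guard window removes the whole signal.")
  out <- vertical
  out[drop] <- approx(keep, vertical[keep], xout = drop, rule = 2)$y
  out
}

#' Per-step gait records and per-recording summary
#'
#' Builds one record per detected step (consecutive IC pair): step time,
#' vertical excursion `D` from [vertical_excursion()], and step length from
#' [step_length()]. Steps whose `D` falls outside `[0, 2 * Wp]` are dropped
#' with a warning. The summary averages over retained steps; the average
#' stride length is exactly twice the average step length, and walking
#' speed is the ratio of the two averages.
#'
#' @param ics A `gait_ics` tibble (>= 3 ICs).
#' @param vertical Gravity-free vertical acceleration (g) for the whole
#'   recording, same indexing as the ICs.
#' @param sampling_rate Sampling frequency in Hz.
#' @param config A [pendulum_config()].
#' @param ic_guard Guard half-width passed to [despike_at_ics()] (default 0:
#'   replace only the IC sample itself); negative to skip despiking.
#' @param drift Drift rule for [vertical_excursion()].
#' @return A list of class `gait_summary` with elements `steps` (per-step
#'   tibble) and `summary` (one-row tibble with `avg_step_time`,
#'   `avg_stride_time`, `avg_step_length`, `avg_stride_length`,
#'   `walking_speed`, `n_steps`, `side`).
#' @export
summarize_gait <- function(ics, vertical, sampling_rate,
                           config = pendulum_config(), ic_guard = 0,
                           drift = "velocity_mean") {
  side <- attr(ics, "side") %||% "left"
  src <- attr(ics, "source_id") %||% "subject"
  if (nrow(ics) < 3) {
    abort(paste0("insufficient data: fewer than 3 initial contacts for subject '",
                 src, "' (", side, ")."))
  }
  v <- vertical
  if (ic_guard >= 0) v <- despike_at_ics(v, ics$ic_index, guard = ic_guard)
  idx <- ics$ic_index
  n_step <- length(idx) - 1
  steps <- purrr::map_dfr(seq_len(n_step), function(i) {
    seg <- v[idx[i]:idx[i + 1]]
    tibble(
      ic_start = ics$ic_time[i],
      ic_end = ics$ic_time[i + 1],
      step_time = ics$ic_time[i + 1] - ics$ic_time[i],
      D = vertical_excursion(seg, sampling_rate, drift = drift)
    )
  })
  ok <- steps$D >= 0 & steps$D <= 2 * config$Wp
  if (any(!ok)) {
    warn(paste0(sum(!ok), " step(s) dropped for subject '", src, "' (", side,
                "): D outside [0, 2*Wp]."))
  }
  steps <- steps[ok, , drop = FALSE]
  if (nrow(steps) < 1) {
    abort(paste0("insufficient data: no valid steps for subject '", src,
                 "' (", side, ")."))
  }
  steps$step_length <- step_length(steps$D, config)
  avg_st <- mean(steps$step_time)
  avg_sl <- mean(steps$step_length)
  summary <- tibble(
    subject_id = src,
    side = side,
    avg_step_time = avg_st,
    avg_stride_time = mean(stride_times(ics)),
    avg_step_length = avg_sl,
    avg_stride_length = 2 * avg_sl,
    walking_speed = walking_speed(avg_sl, avg_st),
    n_steps = nrow(steps)
  )
  structure(list(steps = steps, summary = summary),
            class = "gait_summary",
            sampling_rate = sampling_rate, config = config)
}

#' Combine left and right gait summaries
#'
#' Unweighted mean of the two sides' summary parameters; step counts are
#' summed. The fusion rule is symmetric, so the order of arguments does not
#' matter.
#'
#' @param left,right `gait_summary` objects (or their one-row `summary`
#'   tibbles) for the two sides of one subject.
#' @return A one-row tibble with `side = "combined"`.
#' @export
combine_gait_summaries <- function(left, right) {
  s1 <- if (inherits(left, "gait_summary")) left$summary else left
  s2 <- if (inherits(right, "gait_summary")) right$summary else right
  cols <- c("avg_step_time", "avg_stride_time", "avg_step_length",
            "avg_stride_length", "walking_speed")
  out <- s1
  for (col in cols) out[[col]] <- (s1[[col]] + s2[[col]]) / 2
  out$n_steps <- s1$n_steps + s2$n_steps
  out$side <- "combined"
  out
}
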