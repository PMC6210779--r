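#' Simulate a ground-truthed accelerometer walk
#'
#' Generates a knee-worn triaxial recording of straight walking together
#' with its exact ground truth. Per step, the sensor's vertical
#' centre-of-mass displacement follows a half-sine arc of peak-to-trough
#' height `D` (drawn per step from `N(D_mean, D_sd)` truncated to
#' `[0, 2 * sensor_height)`), so the vertical acceleration is the analytic
#' second derivative of the arc. A one-sample-wide negative transient of
#' `ic_spike_g` g marks each initial contact (the impact artifact that
#' anchors detection). Gravity (1 g) is added, the whole signal is rotated
#' by `tilt_deg` in the sensor x-z plane to emulate imperfect mounting, and
#' white Gaussian noise of `noise_sd` g is added per axis. Quiet standing
#' of `lead_s` seconds precedes and follows the walk.
#'
#' The ground truth records the exact (continuous-time) IC times, per-step
#' times and `D` values, the step lengths implied by the inverted-pendulum
#' formula at the true `D`, and a summary satisfying all model identities
#' exactly (stride length = 2 x step length; stride time = adjacent step
#' times summed; speed = mean step length / mean step time).
#'
#' @param n_steps Number of steps (>= 3; default 30).
#' @param step_time_mean,step_time_sd Step-time distribution in seconds
#'   (defaults 0.55 and 0.02, the scale reported for advanced-PD walking).
#' @param D_mean,D_sd Vertical-excursion distribution in metres (defaults
#'   5 mm and 1 mm).
#' @param tilt_deg Sensor tilt in degrees (default 5).
#' @param noise_sd Additive noise standard deviation in g (default 0.02).
#' @param sampling_rate Sampling frequency in Hz (default 32).
#' @param sensor_height Sensor height above ground in metres (default 0.34).
#' @param KG Pendulum multiplying factor for the truth step lengths
#'   (default 4).
#' @param ic_spike_g Amplitude of the IC transient in g (default 0.5).
#' @param lead_s Quiet lead-in/lead-out duration in seconds (default 1.5).
#' @param side,subject_id,label Recording metadata.
#' @param seed Integer seed; the same seed reproduces the recording and
#'   truth bit-identically.
#' @return A list of class `fog_walk` with elements `recording` (an
#'   [accel_recording]) and `truth` (list: `ic_times`, `step_times`,
#'   `D_values`, `step_lengths`, `summary`).
#' @export
simulate_walk <- function(n_steps = 30, step_time_mean = 0.55,
                          step_time_sd = 0.02, D_mean = 0.005,
                          D_sd = 0.001, tilt_deg = 5, noise_sd = 0.02,
                          sampling_rate = 32, sensor_height = 0.34, KG = 4,
                          ic_spike_g = 0.5, lead_s = 1.5,
                          side = "left", subject_id = "sim", label = "unknown",
                          seed = 1) {
  if (n_steps < 3) abort("parameter error: `n_steps` must be >= 3.")
  if (step_time_mean <= 0) abort("parameter error: `step_time_mean` must be > 0.")
  if (D_mean < 0 || D_mean >= 2 * sensor_height) {
    abort("parameter error: `D_mean` must lie in [0, 2 * sensor_height).")
  }
  if (noise_sd < 0) abort("parameter error: `noise_sd` must be >= 0.")
  set.seed(seed)
  step_t <- pmax(rnorm(n_steps, step_time_mean, step_time_sd), 0.25)
  D <- pmin(pmax(rnorm(n_steps, D_mean, D_sd), 0), 2 * sensor_height * 0.999)
  ic_times <- lead_s + cumsum(c(0, step_t))           # n_steps + 1 contacts
  duration <- ic_times[n_steps + 1] + lead_s
  n <- ceiling(duration * sampling_rate) + 1
  t <- (seq_len(n) - 1) / sampling_rate

  # analytic second derivative of the per-step half-sine arc, in g
  a_dyn <- numeric(n)
  for (j in seq_len(n_steps)) {
    within <- t >= ic_times[j] & t < ic_times[j + 1]
    tau <- t[within] - ic_times[j]
    a_dyn[within] <- -D[j] * (pi / step_t[j])^2 *
      sin(pi * tau / step_t[j]) / GRAVITY_MS2
  }
  spike_idx <- round(ic_times * sampling_rate) + 1
  a_dyn[spike_idx] <- a_dyn[spike_idx] - ic_spike_g

  theta <- tilt_deg * pi / 180
  az0 <- 1 + a_dyn
  ax0 <- numeric(n)
  ax <- ax0 * cos(theta) + az0 * sin(theta) + rnorm(n, 0, noise_sd)
  ay <- rnorm(n, 0, noise_sd)
  az <- -ax0 * sin(theta) + az0 * cos(theta) + rnorm(n, 0, noise_sd)

  rec <- accel_recording(ax, ay, az,
                         sampling_rate = sampling_rate,
                         sensor_height = sensor_height, side = side,
                         subject_id = subject_id, label = label,
                         sensor_sourced = TRUE)
  cfg <- pendulum_config(Wp = sensor_height, KG = KG)
  sl <- step_length(D, cfg)
  truth_summary <- tibble(
    subject_id = subject_id,
    side = side,
    avg_step_time = mean(step_t),
    avg_stride_time = mean(stride_times(ic_times)),
    avg_step_length = mean(sl),
    avg_stride_length = 2 * mean(sl),
    walking_speed = mean(sl) / mean(step_t),
    n_steps = n_steps
  )
  structure(
    list(
      recording = rec,
      truth = list(ic_times = ic_times, step_times = step_t, D_values = D,
                   step_lengths = sl, summary = truth_summary)
    ),
    class = "fog_walk"
  )
}

#' Simulate a labelled two-class feature cohort
#'
#' Draws per-subject 14-feature vectors from a correlated multivariate
#' normal distribution. The noFoG class sits at baseline means on the scale
#' of reported cohort values (step time 0.53 s, stride time 1.17 s, step
#' length 0.38 m, stride length 0.73 m, speed 0.68 m/s); the FoG class is
#' shifted by `effect_size` standard deviations on the designated features,
#' in the direction of impaired gait (longer times, shorter lengths, lower
#' speed). Cross-correlation features are clamped to \[-1, 1\].
#'
#' @param n_fog,n_nofog Class sizes (defaults 36 and 15, mirroring the
#'   study cohort composition).
#' @param effect_size Standardised mean shift applied to the shifted
#'   features (default 1).
#' @param shifted_features Features receiving the shift (default the five
#'   spatiotemporal parameters).
#' @param correlation Common between-feature correlation in \[0, 0.9\]
#'   (default 0.3).
#' @param seed Integer seed.
#' @return A tibble with `subject_id`, `label` and the 14 [feature_names]
#'   columns.
#' @export
simulate_feature_cohort <- function(n_fog = 36, n_nofog = 15,
                                    effect_size = 1,
                                    shifted_features = feature_names[1:5],
                                    correlation = 0.3, seed = 1) {
  if (n_fog < 2 || n_nofog < 2) {
    abort("parameter error: each class needs at least 2 subjects.")
  }
  if (correlation < 0 || correlation > 0.9) {
    abort("parameter error: `correlation` must lie in [0, 0.9].")
  }
  base_mean <- c(
    avg_step_time = 0.53, avg_stride_time = 1.17, avg_step_length = 0.38,
    avg_stride_length = 0.73, walking_speed = 0.68,
    sigma_x = 0.15, sigma_y = 0.12, sigma_z = 0.20,
    S_xy = 0.20, S_xz = 0.25, S_yz = 0.15,
    harmonic_x = 2.0, harmonic_y = 1.8, harmonic_z = 2.2
  )[feature_names]
  base_sd <- c(
    avg_step_time = 0.05, avg_stride_time = 0.10, avg_step_length = 0.05,
    avg_stride_length = 0.10, walking_speed = 0.10,
    sigma_x = 0.04, sigma_y = 0.03, sigma_z = 0.05,
    S_xy = 0.10, S_xz = 0.10, S_yz = 0.10,
    harmonic_x = 0.40, harmonic_y = 0.35, harmonic_z = 0.45
  )[feature_names]
  # impaired gait: times up, lengths and speed down
  direction <- c(
    avg_step_time = 1, avg_stride_time = 1, avg_step_length = -1,
    avg_stride_length = -1, walking_speed = -1,
    sigma_x = 1, sigma_y = 1, sigma_z = 1,
    S_xy = 1, S_xz = 1, S_yz = 1,
    harmonic_x = -1, harmonic_y = -1, harmonic_z = -1
  )[feature_names]
  p <- length(feature_names)
  corr <- matrix(correlation, p, p)
  diag(corr) <- 1
  sigma <- diag(base_sd) %*% corr %*% diag(base_sd)
  shift <- numeric(p)
  names(shift) <- feature_names
  shift[shifted_features] <- effect_size * base_sd[shifted_features] *
    direction[shifted_features]
  set.seed(seed)
  x0 <- MASS::mvrnorm(n_nofog, mu = base_mean, Sigma = sigma)
  x1 <- MASS::mvrnorm(n_fog, mu = base_mean + shift, Sigma = sigma)
  x <- rbind(x1, x0)
  colnames(x) <- feature_names
  for (col in c("S_xy", "S_xz", "S_yz")) {
    x[, col] <- pmin(pmax(x[, col], -1), 1)
  }
  out <- as_tibble(as.data.frame(x))
  dplyr::bind_cols(
    tibble(
      subject_id = sprintf("S%02d", seq_len(n_fog + n_nofog)),
      label = c(rep("FoG", n_fog), rep("noFoG", n_nofog))
    ),
    out
  )
}
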