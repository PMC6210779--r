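#' Names of the 14 gait features, in canonical order
#'
#' Five spatiotemporal parameters, three per-axis standard deviations,
#' three zero-lag cross-axis correlations and three per-axis harmonic
#' ratios.
#'
#' @export
feature_names <- c(
  "avg_step_time", "avg_stride_time", "avg_step_length",
  "avg_stride_length", "walking_speed",
  "sigma_x", "sigma_y", "sigma_z",
  "S_xy", "S_xz", "S_yz",
  "harmonic_x", "harmonic_y", "harmonic_z"
)

#' Per-axis standard deviation of a recording
#'
#' Sample standard deviation (n - 1 denominator) of each raw axis, in g.
#'
#' @param rec An [accel_recording] with at least 2 samples.
#' @return Named numeric vector `c(sigma_x, sigma_y, sigma_z)`.
#' @export
axis_std <- function(rec) {
  if (nrow(rec) < 2) abort("input error: need at least 2 samples.")
  c(sigma_x = sd(rec$ax), sigma_y = sd(rec$ay), sigma_z = sd(rec$az))
}

#' Zero-lag cross-correlation coefficient
#'
#' Normalised cross-correlation of two mean-removed series at lag zero,
#' which equals the product-moment correlation; always in \[-1, 1\].
#'
#' @param a,b Numeric series of equal length >= 2, neither constant.
#' @return Correlation coefficient.
#' @export
zero_lag_crosscorr <- function(a, b) {
  if (length(a) != length(b)) abort("series lengths differ.")
  if (length(a) < 2) abort("need at least 2 samples.")
  if (sd(a) == 0 || sd(b) == 0) {
    abort("undefined correlation: constant series.")
  }
  cor(a, b)
}

#' Harmonic ratio of an acceleration series
#'
#' Splits the series into consecutive strides, extracts the amplitudes of
#' the first `n_harmonics` harmonics of the stride frequency by discrete
#' Fourier analysis of each stride, and forms the ratio of even- to
#' odd-harmonic amplitude sums (vertical/anteroposterior axes, where a
#' symmetric gait concentrates power at even multiples of the stride
#' frequency) or its reciprocal orientation (mediolateral axis). Per-stride
#' ratios are averaged.
#'
#' Harmonics are truncated below the Nyquist frequency; at 32 Hz and a
#' typical stride frequency near 0.9 Hz about 17 of the default 20
#' harmonics are usable.
#'
#' @param x Numeric series covering an integer number of strides.
#' @param stride_frequency Stride frequency in Hz.
#' @param sampling_rate Sampling frequency in Hz.
#' @param n_harmonics Number of harmonics (default 20).
#' @param axis_role `"vertical_or_ap"` (even/odd) or `"ml"` (odd/even).
#' @return Harmonic ratio (>= 0).
#' @export
harmonic_ratio <- function(x, stride_frequency, sampling_rate,
                           n_harmonics = 20,
                           axis_role = c("vertical_or_ap", "ml")) {
  axis_role <- match.arg(axis_role)
  if (stride_frequency <= 0) abort("`stride_frequency` must be positive.")
  len <- round(sampling_rate / stride_frequency)
  if (len < 4 || length(x) < len) {
    abort("signal shorter than one stride at the given stride frequency.")
  }
  n_strides <- floor(length(x) / len)
  ratios <- vapply(seq_len(n_strides), function(s) {
    seg <- x[((s - 1) * len + 1):(s * len)]
    .even_odd_ratio(seg, n_harmonics, axis_role)
  }, numeric(1))
  mean(ratios)
}

# even/odd amplitude-sum ratio of one stride segment
.even_odd_ratio <- function(seg, n_harmonics, axis_role) {
  len <- length(seg)
  kmax <- min(n_harmonics, floor((len - 1) / 2))
  amps <- Mod(fft(seg))[2:(kmax + 1)] * 2 / len
  k <- seq_len(kmax)
  even <- sum(amps[k %% 2 == 0])
  odd <- sum(amps[k %% 2 == 1])
  num <- if (axis_role == "vertical_or_ap") even else odd
  den <- if (axis_role == "vertical_or_ap") odd else even
  if (den <= 1e-9 * (num + den)) {
    abort("degenerate signal: zero-amplitude harmonic denominator.")
  }
  num / den
}

#' Assemble the 14-feature gait vector for one subject
#'
#' Combines the five spatiotemporal averages from a gait summary with nine
#' signal features computed on the raw recording axes: per-axis standard
#' deviations, zero-lag cross-axis correlations, and per-axis harmonic
#' ratios at the stride frequency `1 / avg_stride_time`. Harmonic ratios
#' are computed on the stride-aligned portion of the signal starting at the
#' first initial contact. The knee sensor's x and z axes move mostly in the
#' progression/vertical plane and use the even/odd orientation; y is
#' treated as mediolateral.
#'
#' @param summary A `gait_summary` (or its one-row summary tibble).
#' @param rec The [accel_recording] the summary came from.
#' @param ics The `gait_ics` series for the recording (>= 3 ICs).
#' @param n_harmonics Harmonics used for the harmonic ratios (default 20).
#' @return A one-row tibble with the 14 columns of [feature_names], in
#'   order, plus `subject_id` and `label` first.
#' @export
assemble_features <- function(summary, rec, ics, n_harmonics = 20) {
  s <- if (inherits(summary, "gait_summary")) summary$summary else summary
  if (nrow(ics) < 3) abort("assembly error: need >= 3 ICs for stride frequency.")
  fs <- sampling_rate(rec)
  sig <- axis_std(rec)
  cc <- c(
    S_xy = tryCatch(zero_lag_crosscorr(rec$ax, rec$ay),
                    error = function(e) abort(paste0("S_xy: ", conditionMessage(e)))),
    S_xz = tryCatch(zero_lag_crosscorr(rec$ax, rec$az),
                    error = function(e) abort(paste0("S_xz: ", conditionMessage(e)))),
    S_yz = tryCatch(zero_lag_crosscorr(rec$ay, rec$az),
                    error = function(e) abort(paste0("S_yz: ", conditionMessage(e))))
  )
  f_stride <- 1 / s$avg_stride_time
  from <- ics$ic_index[1]
  hr <- vapply(c(x = "ax", y = "ay", z = "az"), function(axis) {
    role <- if (axis == "ay") "ml" else "vertical_or_ap"
    x <- rec[[axis]][from:nrow(rec)]
    harmonic_ratio(x - mean(x), f_stride, fs,
                   n_harmonics = n_harmonics, axis_role = role)
  }, numeric(1))
  out <- tibble(
    subject_id = s$subject_id %||% attr(rec, "subject_id"),
    label = attr(rec, "label") %||% "unknown",
    avg_step_time = s$avg_step_time,
    avg_stride_time = s$avg_stride_time,
    avg_step_length = s$avg_step_length,
    avg_stride_length = s$avg_stride_length,
    walking_speed = s$walking_speed,
    sigma_x = sig[["sigma_x"]], sigma_y = sig[["sigma_y"]],
    sigma_z = sig[["sigma_z"]],
    S_xy = cc[["S_xy"]], S_xz = cc[["S_xz"]], S_yz = cc[["S_yz"]],
    harmonic_x = hr[["x"]], harmonic_y = hr[["y"]], harmonic_z = hr[["z"]]
  )
  stopifnot(all(feature_names %in% names(out)))
  out
}

#' Augment a 14-feature matrix with all 14 principal components
#'
#' Standardises the training features (they carry heterogeneous units), fits
#' a PCA on the standardised training matrix, and appends all 14
#' principal-component scores to the original features, giving the
#' 28-dimensional classification vector. With all components retained the
#' explained variance is 100% of the standardised training variance (the
#' retained set always exceeds the conventional 95% threshold). The
#' transform (training means, standard deviations, loadings) is frozen from
#' `train` and applied unchanged to `apply`, so no information leaks from
#' evaluation rows. Loading signs are fixed so the largest-magnitude loading
#' of each component is positive.
#'
#' @param train Data frame or matrix of training rows with the 14
#'   [feature_names] columns; at least 15 rows.
#' @param newdata Rows to transform (defaults to `train`).
#' @return A tibble of class `fog_augmented` with the 14 original columns
#'   followed by `pc1`..`pc14` (28 feature columns; `subject_id`/`label`
#'   columns of `newdata` are carried through in front). Attributes:
#'   `transform` (list with `center`, `scale`, `rotation`, `sdev`) and
#'   `explained_variance` (fractions summing to 1).
#' @export
pca_augment <- function(train, newdata = train) {
  xt <- .feature_matrix(train)
  xa <- .feature_matrix(newdata)
  if (nrow(xt) < ncol(xt) + 1) {
    abort("training matrix needs at least 15 rows (one more than features).")
  }
  ctr <- colMeans(xt)
  scl <- apply(xt, 2, sd)
  if (any(scl == 0)) {
    abort(paste0("zero-variance training feature(s): ",
                 paste(colnames(xt)[scl == 0], collapse = ", ")))
  }
  zt <- scale(xt, center = ctr, scale = scl)
  pc <- stats::prcomp(zt, center = FALSE, scale. = FALSE)
  rot <- pc$rotation
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  tol <- max(pc$sdev) * 1e-9
  if (any(pc$sdev < tol)) {
    warn("rank-deficient training matrix: trailing components carry zero variance.")
  }
  za <- scale(xa, center = ctr, scale = scl)
  scores <- za %*% rot
  colnames(scores) <- paste0("pc", seq_len(ncol(scores)))
  meta <- if (is.data.frame(newdata)) {
    newdata[setdiff(names(newdata), feature_names)]
  } else NULL
  out <- dplyr::bind_cols(
    if (!is.null(meta) && ncol(meta) > 0) as_tibble(meta),
    as_tibble(as.data.frame(xa)),
    as_tibble(as.data.frame(scores))
  )
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(out,
            class = c("fog_augmented", class(out)),
            transform = list(center = ctr, scale = scl, rotation = rot,
                             sdev = pc$sdev),
            explained_variance = ev)
}

# Extract the 14 feature columns as a numeric matrix, in canonical order.
.feature_matrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 14) abort("feature matrix must have 14 columns.")
    if (is.null(colnames(x))) colnames(x) <- feature_names
    return(x[, feature_names, drop = FALSE])
  }
  missing_cols <- setdiff(feature_names, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing feature column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  as.matrix(x[feature_names])
}
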