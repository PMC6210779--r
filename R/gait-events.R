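#' Smooth an acceleration series by integration
#'
#' Cumulative trapezoidal integration followed by linear detrending. The
#' 1/f response of integration suppresses high-frequency content while the
#' detrend removes the ramp that an offset would otherwise produce.
#'
#' @param x Numeric series (uniformly sampled).
#' @param sampling_rate Sampling frequency in Hz.
#' @return Numeric series of the same length.
#' @export
smooth_by_integration <- function(x, sampling_rate) {
  if (length(x) < 2) abort("input error: need at least 2 samples.")
  if (!all(is.finite(x))) abort("input error: non-finite values in series.")
  y <- as.numeric(pracma::cumtrapz(x)) / sampling_rate
  as.numeric(pracma::detrend(y, tt = "linear"))
}

#' First derivative via a Gaussian continuous wavelet transform
#'
#' Convolves the series with a first-derivative-of-Gaussian kernel of the
#' given scale (in samples), i.e. the derivative of the Gaussian-smoothed
#' series. The kernel is normalised so that a linear ramp of slope m (per
#' second) maps to a constant interior value of m; a rising ramp gives
#' positive output. The kernel half-width `ceiling(4 * scale)` samples at
#' each end is edge-affected and is flagged via the `edge_samples`
#' attribute.
#'
#' @param x Numeric series.
#' @param sampling_rate Sampling frequency in Hz.
#' @param scale Gaussian scale in samples (>= 1).
#' @return Numeric series of the same length with attributes `scale` and
#'   `edge_samples`.
#' @export
gaussian_cwt_derivative <- function(x, sampling_rate, scale) {
  if (scale < 1) abort("parameter error: `scale` must be >= 1.")
  n <- length(x)
  if (n <= 10 * scale) {
    abort("parameter error: `scale` too large for the signal length.")
  }
  half <- ceiling(4 * scale)
  m <- seq(-half, half)
  k <- -m / (scale^3 * sqrt(2 * pi)) * exp(-m^2 / (2 * scale^2))
  full <- convolve(x, rev(k), type = "open")
  out <- full[(half + 1):(half + n)] * sampling_rate
  structure(out, scale = scale, edge_samples = half)
}

#' Dominant step frequency of a vertical acceleration series
#'
#' Periodogram argmax restricted to the 0.5-3 Hz walking band; used to tie
#' the event-detection smoothing scale to the subject's cadence.
#'
#' @param x Vertical acceleration series (g, gravity removed).
#' @param sampling_rate Sampling frequency in Hz.
#' @param band Frequency band searched, Hz.
#' @return Frequency in Hz.
#' @export
dominant_step_frequency <- function(x, sampling_rate, band = c(0.5, 3)) {
  sp <- stats::spec.pgram(x, plot = FALSE, detrend = TRUE, taper = 0)
  freq <- sp$freq * sampling_rate
  keep <- freq >= band[1] & freq <= band[2]
  if (!any(keep)) abort("no periodogram support in the walking band.")
  freq[keep][which.max(sp$spec[keep])]
}

#' Detect initial contacts (heel strikes)
#'
#' Takes the processed series produced by [smooth_by_integration()] followed
#' by [gaussian_cwt_derivative()] — together equivalent to Gaussian-smoothing
#' the acceleration — and returns its local minima as initial contacts.
#' Candidate minima must have prominence at least `prominence_frac` times
#' the standard deviation of the processed series and be separated by at
#' least `min_separation_s`; when two candidates conflict, the deeper (more
#' negative) one wins, ties going to the earlier index. Minima inside the
#' edge-affected region are discarded.
#'
#' @param processed Numeric series (output of the smoothing chain).
#' @param sampling_rate Sampling frequency in Hz.
#' @param prominence_frac Prominence threshold as a fraction of `sd(processed)`
#'   (default 0.5).
#' @param min_separation_s Minimum spacing between contacts in seconds
#'   (default 0.25).
#' @param edge_samples Number of samples at each end to exclude; defaults to
#'   the `edge_samples` attribute left by [gaussian_cwt_derivative()], else 0.
#' @param side,source_id Metadata carried into the result.
#' @return A tibble of class `gait_ics` with columns `ic_index` (1-based
#'   sample index) and `ic_time` (seconds, `(ic_index - 1) / sampling_rate`
#'   exactly), strictly increasing.
#' @export
detect_initial_contacts <- function(processed, sampling_rate,
                                    prominence_frac = 0.5,
                                    min_separation_s = 0.25,
                                    edge_samples = NULL,
                                    side = "left", source_id = "subject") {
  if (!is.numeric(prominence_frac) || prominence_frac < 0 ||
      !is.numeric(min_separation_s) || min_separation_s < 0) {
    abort("parameter error: invalid detection config.")
  }
  edge <- edge_samples %||% attr(processed, "edge_samples") %||% 0L
  x <- as.numeric(processed)
  n <- length(x)
  empty <- structure(
    tibble(ic_index = integer(), ic_time = numeric()),
    class = c("gait_ics", class(tibble())),
    sampling_rate = sampling_rate, side = side, source_id = source_id
  )
  if (n < 3) return(empty)
  # the edge-affected ends carry large convolution transients; the reference
  # scale for the prominence threshold is the sd of the reliable interior
  interior <- x[min(edge + 1, n):max(n - edge, 1)]
  if (sd(interior) == 0) return(empty)
  cand <- which(x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] <= x[3:n]) + 1L
  cand <- cand[cand > edge & cand <= n - edge]
  if (length(cand) == 0) return(empty)
  prom <- vapply(cand, .min_prominence, numeric(1), x = x)
  cand <- cand[prom >= prominence_frac * sd(interior)]
  if (length(cand) == 0) return(empty)
  # greedy: deepest first, earlier index breaks ties
  ord <- order(x[cand], cand)
  min_gap <- min_separation_s * sampling_rate
  kept <- integer()
  for (i in cand[ord]) {
    if (all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  structure(
    tibble(ic_index = kept, ic_time = (kept - 1) / sampling_rate),
    class = c("gait_ics", class(tibble())),
    sampling_rate = sampling_rate, side = side, source_id = source_id
  )
}

# Prominence of a local minimum at index i: on each side, walk to the
# nearest point lower than x[i] (or the series end) and record the highest
# value passed; prominence is the smaller of the two heights above x[i].
.min_prominence <- function(i, x) {
  v <- x[i]
  side_height <- function(idx) {
    h <- -Inf
    for (j in idx) {
      if (x[j] < v) return(h)
      if (x[j] > h) h <- x[j]
    }
    h
  }
  lmax <- side_height(rev(seq_len(i - 1)))
  rmax <- side_height(seq(i + 1, length(x)))
  min(lmax, rmax) - v
}

#' Detect initial contacts from an aligned signal
#'
#' Convenience wrapper chaining [lowpass_filter()] (if not already applied),
#' [smooth_by_integration()], [gaussian_cwt_derivative()] and
#' [detect_initial_contacts()] on the vertical component.
#'
#' The smoothing scale defaults to `"auto"`: `sampling_rate / (6 * f_step)`
#' samples (at least 2), with `f_step` the dominant walking-band frequency
#' from [dominant_step_frequency()]. Tying the scale to cadence keeps the
#' smoothing proportionate to the step period; the fraction is deliberately
#' small because adjacent contact responses coalesce once the Gaussian
#' width approaches half the contact spacing, and because the timing
#' jitter of a smoothed transient grows with the smoothing width.
#'
#' @param aligned An `accel_aligned` tibble (see
#'   [realign_to_horizontal_vertical()]).
#' @param scale `"auto"` or a Gaussian scale in samples.
#' @param filter_first Apply the default low-pass filter before processing
#'   (default TRUE).
#' @inheritParams detect_initial_contacts
#' @return A `gait_ics` tibble.
#' @export
find_initial_contacts <- function(aligned, scale = "auto",
                                  prominence_frac = 0.5,
                                  min_separation_s = 0.25,
                                  filter_first = TRUE) {
  stopifnot(inherits(aligned, "accel_aligned"))
  fs <- sampling_rate(aligned)
  v <- aligned$vertical
  if (filter_first) v <- lowpass_filter(v, fs)
  if (identical(scale, "auto")) {
    f_step <- dominant_step_frequency(v, fs)
    scale <- max(2, round(fs / (6 * f_step)))
  }
  sm <- smooth_by_integration(v, fs)
  dv <- gaussian_cwt_derivative(sm, fs, scale)
  detect_initial_contacts(dv, fs,
                          prominence_frac = prominence_frac,
                          min_separation_s = min_separation_s,
                          side = attr(aligned, "side") %||% "left",
                          source_id = attr(aligned, "source_id") %||% "subject")
}
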