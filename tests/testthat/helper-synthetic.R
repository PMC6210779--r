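# Shared fixtures: everything is generated in code at test time.

# low-pass with the package defaults, silencing the near-Nyquist warning
# that the 15 Hz / 32 Hz combination intentionally raises
quiet_lowpass <- function(x, ...) suppressWarnings(lowpass_filter(x, ...))

# full processing chain on a recording, warnings (near-Nyquist, dropped
# steps) silenced
quiet_process <- function(rec, ...) suppressWarnings(process_recording(rec, ...))

# per-true-IC matching error in samples
ic_match_errors <- function(ics, truth_times, fs = 32) {
  vapply(truth_times, function(t) min(abs(ics$ic_time - t)), numeric(1)) * fs
}

# detected-IC distance to nearest true IC, in samples
ic_spurious_distances <- function(ics, truth_times, fs = 32) {
  vapply(ics$ic_time, function(t) min(abs(truth_times - t)), numeric(1)) * fs
}

# a recording holding given axis columns at 32 Hz
static_recording <- function(ax, ay, az, n = 80, fs = 32) {
  accel_recording(rep(ax, n), rep(ay, n), rep(az, n), sampling_rate = fs)
}
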