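test_that("read_recording parses delimited files and rebuilds the time base", {
  path <- withr::local_tempfile(fileext = ".csv")
  n <- 60 * 32
  rec0 <- accel_recording(rnorm(n, 0, 0.1), rnorm(n, 0, 0.1),
                          1 + rnorm(n, 0, 0.1))
  write_recording(rec0, path)
  rec <- read_recording(path, sampling_rate = 32)
  expect_equal(nrow(rec), 1920)
  expect_equal(sampling_rate(rec), 32)
  # round trip is bit-identical
  expect_identical(rec$ax, rec0$ax)
  expect_identical(rec$az, rec0$az)
  expect_equal(rec$time, (seq_len(n) - 1) / 32)
})

test_that("read_recording rejects malformed input", {
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ax,ay", "0.1,0.2", "0.1,0.2"), bad)
  expect_error(read_recording(bad), "missing axis column")

  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ax,ay,az", "0.1,0.2,0.3", "0.1,oops,0.3"), bad2)
  expect_error(read_recording(bad2), "row 2")

  short <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ax,ay,az", "0.1,0.2,0.3"), short)
  expect_error(read_recording(short), "fewer than 2")

  jitter <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,ax,ay,az", "0,0,0,1", "0.2,0,0,1", "0.25,0,0,1"), jitter)
  expect_error(read_recording(jitter), "uniform")
})

test_that("recording invariants are enforced", {
  expect_error(accel_recording(1, 1, 1), "at least 2")
  expect_error(accel_recording(c(0, NA), c(0, 0), c(1, 1)), "finite")
  expect_error(accel_recording(c(0, 9), c(0, 0), c(1, 1),
                               sensor_sourced = TRUE), "8")
  expect_silent(accel_recording(c(0, 7.9), c(0, 0), c(1, 1),
                                sensor_sourced = TRUE))
})

test_that("realignment maps a static tilted recording onto gravity", {
  # already aligned: vertical and horizontals all zero after gravity removal
  flat <- realign_to_horizontal_vertical(static_recording(0, 0, 1))
  expect_lt(max(abs(flat$vertical)), 1e-12)
  expect_lt(max(abs(flat$ap)), 1e-12)
  expect_lt(max(abs(flat$ml)), 1e-12)

  # constant gravity tilted 10 degrees in the x-z plane: rotated vertical is
  # exactly 1 g before subtraction, zero after; horizontals vanish
  th <- 10 * pi / 180
  tilted <- realign_to_horizontal_vertical(
    static_recording(sin(th), 0, cos(th))
  )
  expect_lt(max(abs(tilted$vertical)), 1e-9)   # (z'' - 1) with z'' = 1
  expect_lt(max(abs(tilted$ap)), 1e-9)
  expect_lt(max(abs(tilted$ml)), 1e-9)
})

test_that("realignment preserves per-sample norms and inverts exactly", {
  set.seed(42)
  n <- 128
  rec <- accel_recording(rnorm(n, 0.1, 0.05), rnorm(n, -0.05, 0.05),
                         rnorm(n, 0.98, 0.05))
  al <- realign_to_horizontal_vertical(rec)
  norm_raw <- sqrt(rec$ax^2 + rec$ay^2 + rec$az^2)
  norm_rot <- sqrt(al$ap^2 + al$ml^2 + (al$vertical + 1)^2)
  expect_lt(max(abs(norm_rot - norm_raw)), 1e-9)
  back <- unrealign(al)
  expect_lt(max(abs(back$ax - rec$ax)), 1e-9)
  expect_lt(max(abs(back$ay - rec$ay)), 1e-9)
  expect_lt(max(abs(back$az - rec$az)), 1e-9)
})

test_that("realignment rejects implausible gravity references", {
  expect_error(realign_to_horizontal_vertical(static_recording(0, 0, 0.2)),
               "orientation-estimation")
  expect_error(realign_to_horizontal_vertical(static_recording(0, 0, 1.8)),
               "orientation-estimation")
  short <- accel_recording(rep(0, 32), rep(0, 32), rep(1, 32))
  expect_error(realign_to_horizontal_vertical(short), "2 s")
})

test_that("low-pass filter has unit DC gain and zero-phase behaviour", {
  const <- rep(0.7, 200)
  expect_lt(max(abs(quiet_lowpass(const, 32) - 0.7)), 1e-9)

  # band-limited content passes essentially unchanged (passband idempotence)
  t <- (0:511) / 32
  slow <- 0.1 * sin(2 * pi * 1 * t)
  once <- quiet_lowpass(slow, 32)
  expect_lt(max(abs(once - slow)), 1e-3)
  expect_lt(max(abs(quiet_lowpass(once, 32) - once)), 1e-3)
})

test_that("filter attenuation matches the analytic Butterworth response", {
  # tone well above an artificially low cutoff; forward-backward filtering
  # squares the order-4 magnitude response
  fs <- 1000; f0 <- 10; fc <- 2
  t <- (0:(20 * fs - 1)) / fs
  x <- sin(2 * pi * f0 * t)
  y <- lowpass_filter(x, fs, order = 4, cutoff = fc)
  core <- seq(5 * fs, 15 * fs)   # steady-state region
  amp <- 2 * sqrt(mean(y[core] * sin(2 * pi * f0 * t[core]))^2 +
                  mean(y[core] * cos(2 * pi * f0 * t[core]))^2)
  expected <- 1 / (1 + (f0 / fc)^(2 * 4))   # |H|^2 at f0
  expect_lt(abs(amp / expected - 1), 0.05)
})

test_that("filter parameter validation", {
  expect_error(lowpass_filter(rnorm(100), 32, cutoff = 16), "parameter error")
  expect_error(lowpass_filter(rnorm(100), 32, cutoff = 20), "parameter error")
  expect_warning(lowpass_filter(rnorm(100), 32, cutoff = 15), "Nyquist")
  expect_error(lowpass_filter(rnorm(10), 32, order = 4, cutoff = 5), "short")
})
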