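test_that("step and stride times follow the contact-differencing identities", {
  expect_equal(step_times(c(0, 0.5, 1.1)), c(0.5, 0.6))
  expect_equal(stride_times(c(0, 0.5, 1.1)), 1.1)
  expect_equal(step_times(0.3), numeric())
  expect_equal(stride_times(c(0, 0.5)), numeric())

  # uniform contacts at the cohort-mean step time
  ics <- cumsum(c(0, rep(0.53, 10)))
  expect_equal(step_times(ics), rep(0.53, 10))
  expect_equal(stride_times(c(0, 0.57, 1.13, 1.70)), c(1.13, 1.13))

  # stride(i) = step(i) + step(i+1), exactly, for arbitrary series
  set.seed(11)
  for (rep in 1:5) {
    t <- cumsum(runif(12, 0.4, 0.8))
    st <- step_times(t)
    expect_identical(stride_times(t), st[-length(st)] + st[-1])
  }
})

test_that("vertical excursion recovers closed-form displacements", {
  fs <- 32
  expect_equal(vertical_excursion(rep(0, 20), fs), 0)

  # a(t) = -A w^2 sin(wt) over one full period -> displacement A sin(wt),
  # excursion 2A
  A <- 0.005; f <- 1
  t <- seq(0, 1, by = 1 / fs)
  a <- -A * (2 * pi * f)^2 * sin(2 * pi * f * t) / 9.80665
  expect_lt(abs(vertical_excursion(a, fs) / (2 * A) - 1), 0.05)

  # half-sine arch spanning the segment (the pendulum waveform) is
  # preserved by the default drift rule
  T_step <- 0.5; D <- 0.008
  tau <- seq(0, T_step, by = 1 / fs)
  arch <- -D * (pi / T_step)^2 * sin(pi * tau / T_step) / 9.80665
  expect_lt(abs(vertical_excursion(arch, fs) / D - 1), 0.05)

  # constant bias is annihilated by the velocity-linear drift rule
  seg <- rep(0.01, 17)   # 0.01 g over a 0.5 s step
  expect_lt(vertical_excursion(seg, fs, drift = "velocity_linear"), 1e-4)

  expect_error(vertical_excursion(c(0, 0, 0), fs), "input error")
  expect_error(vertical_excursion(c(0, NA, 0, 0), fs), "input error")
})

test_that("pendulum step length matches its closed form and domain", {
  cfg <- pendulum_config(Wp = 0.34, KG = 4)
  expect_equal(step_length(0, cfg), 0)
  expect_equal(step_length(2 * 0.34, cfg), 0)
  expect_equal(step_length(0.01, cfg), 4 * 2 * sqrt(0.0068 - 0.0001),
               tolerance = 1e-9)
  expect_equal(step_length(0.01, cfg), 0.654829, tolerance = 1e-5)
  expect_error(step_length(-0.001, cfg), "domain error")
  expect_error(step_length(0.7, cfg), "domain error")

  # strictly increasing on (0, Wp)
  grid <- seq(0.001, 0.339, length.out = 400)
  expect_true(all(diff(step_length(grid, cfg)) > 0))

  # doubling KG doubles lengths and speed for fixed events
  cfg2 <- pendulum_config(Wp = 0.34, KG = 8)
  expect_equal(step_length(grid, cfg2), 2 * step_length(grid, cfg))
})

test_that("stride length and walking speed are exact arithmetic", {
  expect_identical(stride_length(0), 0)
  expect_identical(stride_length(0.35), 0.7)
  x <- runif(20)
  expect_identical(stride_length(x), 2 * x)
  expect_error(stride_length(-1), "domain error")

  expect_equal(walking_speed(0.6, 0.5), 1.2)
  expect_equal(walking_speed(0.35, 0.57), 0.6140, tolerance = 1e-4)
  expect_equal(walking_speed(0, 0.5), 0)
  expect_error(walking_speed(0.6, 0), "domain error")
})

test_that("gait summary satisfies the model identities on a uniform walk", {
  w <- simulate_walk(n_steps = 20, step_time_mean = 0.55, step_time_sd = 0,
                     D_mean = 0.006, D_sd = 0, tilt_deg = 0, noise_sd = 0,
                     seed = 2)
  al <- quiet_lowpass(realign_to_horizontal_vertical(w$recording))
  ics <- find_initial_contacts(al, filter_first = FALSE)
  g <- summarize_gait(ics, al$vertical, 32)
  expect_equal(g$summary$avg_step_time, 0.55, tolerance = 1 / 32)
  expect_equal(g$summary$avg_stride_time, 1.10, tolerance = 2 / 32)
  expect_identical(g$summary$avg_stride_length, 2 * g$summary$avg_step_length)
  expect_equal(g$summary$walking_speed,
               g$summary$avg_step_length / g$summary$avg_step_time)
  expect_equal(tidy(g), g$steps)
  expect_equal(glance(g), g$summary)
})

test_that("too few contacts raise an informative error", {
  ics <- structure(
    tibble::tibble(ic_index = c(10L, 30L), ic_time = c(10, 30) / 32),
    class = c("gait_ics", class(tibble::tibble())),
    sampling_rate = 32, side = "right", source_id = "P01"
  )
  expect_error(summarize_gait(ics, rnorm(100, 0, 0.01), 32),
               "P01.*right|insufficient")
})

test_that("left/right summaries combine as unweighted means", {
  s1 <- tibble::tibble(subject_id = "a", side = "left", avg_step_time = 0.5,
                       avg_stride_time = 1.0, avg_step_length = 0.3,
                       avg_stride_length = 0.6, walking_speed = 0.6,
                       n_steps = 10)
  s2 <- dplyr::mutate(s1, side = "right", avg_step_time = 0.6,
                      avg_stride_time = 1.2, avg_step_length = 0.4,
                      avg_stride_length = 0.8, walking_speed = 2 / 3,
                      n_steps = 12)
  comb <- combine_gait_summaries(s1, s2)
  expect_equal(comb$avg_step_time, 0.55)
  expect_equal(comb$avg_step_length, 0.35)
  expect_equal(comb$avg_stride_length, 0.7)
  expect_equal(comb$n_steps, 22)
  expect_equal(comb$side, "combined")
  # symmetric
  expect_equal(combine_gait_summaries(s2, s1)$avg_step_time, 0.55)
})
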