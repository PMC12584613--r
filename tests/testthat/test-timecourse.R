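test_that("a constant-concentration series quantifies to a flat curve", {
  m <- exact_calibration()
  p <- kinetic_profile(c0 = 49.9, c_max = 50, t_mid = -1e3, rate = 1)
  # c(t) ~ 50 for all sampled times
  tc <- quantify_timecourse(
    simulate_timecourse(p, c(0, 10, 20), replicates = 2, noise_sd = 4, seed = 3),
    m, preprocess = FALSE)
  expect_true(all(abs(tc$mean - 50) < 1))
  expect_true(all(tc$n == 2))
})

test_that("a logistic light profile yields a nondecreasing fitted curve", {
  m <- exact_calibration()
  p <- kinetic_profile(c0 = 30, c_max = 70, t_mid = 40, rate = 0.15)
  tc <- quantify_timecourse(
    simulate_timecourse(p, seq(0, 80, by = 10), replicates = 3, seed = 11),
    m, preprocess = FALSE, condition = "light")
  truth <- profile_concentration(p, seq(0, 80, by = 10))
  expect_lt(max(abs(tc$mean - truth)), 1)
  expect_true(all(diff(tc$mean) > -1))

  expect_error(quantify_timecourse(list(list(time = 0, spectra = list())), m),
               "no replicate spectra")
})

test_that("max_rate finds sliding-window slopes with deterministic ties", {
  lin <- structure(data.frame(time = 0:5, mean = 0.5 * (0:5)),
                   class = c("raman_timecourse", "data.frame"))
  r <- max_rate(lin)
  expect_equal(r$rate, 0.5, tolerance = 1e-12)
  expect_equal(r$time, 1)   # earliest window on ties

  flat <- structure(data.frame(time = 0:5, mean = rep(2, 6)),
                    class = c("raman_timecourse", "data.frame"))
  expect_equal(max_rate(flat)$rate, 0, tolerance = 1e-12)

  # invariant to adding a constant concentration offset
  shifted <- lin; shifted$mean <- shifted$mean + 100
  expect_equal(max_rate(shifted)$rate, 0.5, tolerance = 1e-12)

  expect_error(max_rate(lin[1:2, ]), "fewer time points")
  expect_error(max_rate(lin, window_points = 1), ">= 2")
})

test_that("condition comparison is symmetric and respects time dilation", {
  tc <- structure(data.frame(time = seq(0, 80, 10),
                             mean = 30 + 40 / (1 + exp(-0.15 * (seq(0, 80, 10) - 40)))),
                  class = c("raman_timecourse", "data.frame"))
  same <- compare_conditions(tc, tc)
  expect_equal(same$rate_ratio, 1, tolerance = 1e-12)
  expect_equal(same$light_midpoint_time, same$dark_midpoint_time)

  # dark = light with the time axis dilated 2x -> half the max rate
  dilated <- tc; dilated$time <- tc$time * 2
  cmpr <- compare_conditions(tc, dilated)
  expect_equal(cmpr$rate_ratio, 2, tolerance = 1e-9)
  expect_lt(cmpr$light_midpoint_time, cmpr$dark_midpoint_time)

  # label swap exchanges the fields
  swapped <- compare_conditions(dilated, tc)
  expect_equal(swapped$light_rate, cmpr$dark_rate)
  expect_equal(swapped$dark_midpoint_time, cmpr$light_midpoint_time)
})

test_that("paired light/dark simulation orders rates and midpoints", {
  m <- exact_calibration()
  times <- seq(0, 80, by = 10)
  light <- quantify_timecourse(
    simulate_timecourse(kinetic_profile(light_factor = 1), times,
                        replicates = 2, seed = 21), m,
    preprocess = FALSE, condition = "light")
  dark <- quantify_timecourse(
    simulate_timecourse(kinetic_profile(light_factor = 0.4), times,
                        replicates = 2, seed = 22), m,
    preprocess = FALSE, condition = "dark")
  cmpr <- compare_conditions(light, dark)
  expect_gt(cmpr$light_rate, cmpr$dark_rate)
  expect_lt(cmpr$light_midpoint_time, cmpr$dark_midpoint_time)
  expect_gt(cmpr$rate_ratio, 1)
})

test_that("time courses export as tidy CSV", {
  m <- exact_calibration()
  tc <- quantify_timecourse(
    simulate_timecourse(kinetic_profile(), c(0, 40, 80), replicates = 2,
                        noise_sd = 0, seed = 1),
    m, preprocess = FALSE, condition = "light")
  path <- withr::local_tempfile(fileext = ".csv")
  write_timecourse(tc, path)
  got <- utils::read.csv(path)
  expect_equal(names(got), c("condition", "time", "mean", "sd", "n",
                             "extrapolated"))
  expect_equal(got$mean, tc$mean, tolerance = 1e-12)
})
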