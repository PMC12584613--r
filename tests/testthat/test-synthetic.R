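test_that("simulate_spectrum reproduces band peaks, baselines, determinism", {
  s <- isolated_band_spectrum(980, 8, 1000)
  expect_equal(max(s$intensity), 1000)
  expect_equal(s$wavenumber[which.max(s$intensity)], 980)

  flat <- simulate_spectrum(scene_truth(baseline_coeffs = 5))
  expect_true(all(flat$intensity == 5))

  truth <- scene_truth(default_interface_bands(50), noise_sd = 2, seed = 42)
  expect_identical(simulate_spectrum(truth)$intensity,
                   simulate_spectrum(truth)$intensity)
  # a different seed changes the noise realization
  truth2 <- scene_truth(default_interface_bands(50), noise_sd = 2, seed = 43)
  expect_false(identical(simulate_spectrum(truth)$intensity,
                         simulate_spectrum(truth2)$intensity))
})

test_that("simulate_spectrum leaves the global RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_spectrum(scene_truth(noise_sd = 1, seed = 7)))
  expect_identical(.Random.seed, before)
})

test_that("default interface band table encodes the calibration line", {
  only_n2 <- default_interface_bands(0)
  expect_length(only_n2, 1L)
  expect_equal(only_n2[[1L]]$name, "N2")

  bands <- default_interface_bands(50)
  a <- sapply(bands, function(b) gaussian_area(b$height, b$fwhm))
  names(a) <- sapply(bands, `[[`, "name")
  expect_equal(unname(a["sulfate"] / a["N2"]), 0.01802 * 50 - 0.04239,
               tolerance = 1e-12)

  ratio_at <- function(C) {
    b <- default_interface_bands(C)
    a <- sapply(b, function(x) gaussian_area(x$height, x$fwhm))
    a[2] / a[1]
  }
  expect_true(ratio_at(75) > ratio_at(50))
  expect_true(ratio_at(50) > ratio_at(25))
  expect_error(default_interface_bands(50, carotenoid_level = -1), ">= 0")
  expect_error(default_interface_bands(120), "0, 100")
})

test_that("band-area bookkeeping: trapezoid equals analytic area", {
  # property over a spread of band shapes, zero noise and baseline
  cases <- expand.grid(center = c(470, 980, 1523, 2332),
                       fwhm = c(6, 10, 16), height = c(10, 1000))
  for (i in seq_len(nrow(cases))) {
    b <- raman_band("b", cases$center[i], cases$fwhm[i], cases$height[i])
    s <- simulate_spectrum(scene_truth(list(b)))
    w <- c(b$center - 5 * b$fwhm, b$center + 5 * b$fwhm)
    expect_equal(peak_area_numeric(s, w, local_baseline = FALSE),
                 gaussian_area(b$height, b$fwhm), tolerance = 1e-6)
  }
})

test_that("calibration series has the right shape and determinism", {
  series <- simulate_calibration_series(replicates = 3, seed = 42)
  expect_length(series, 15L)
  expect_equal(unique(sapply(series, `[[`, "conc")), c(25, 37.5, 50, 62.5, 75))

  series2 <- simulate_calibration_series(replicates = 3, seed = 42)
  expect_identical(lapply(series, function(e) e$spectrum$intensity),
                   lapply(series2, function(e) e$spectrum$intensity))

  quiet <- simulate_calibration_series(concs = c(30, 50, 70), replicates = 2,
                                       noise_sd = 0, seed = 1)
  expect_identical(quiet[[1L]]$spectrum$intensity, quiet[[2L]]$spectrum$intensity)

  oor <- simulate_calibration_series(concs = c(10, 50, 75), replicates = 1,
                                     seed = 1)
  expect_true(isTRUE(oor[[1L]]$spectrum$meta$out_of_range))
  expect_null(oor[[2L]]$spectrum$meta$out_of_range)
})

test_that("colony map geometry matches disc membership", {
  ax <- seq(300, 2400, by = 2)
  # 11x11 grid, radius covering the 3x3 center block only
  sim <- simulate_map(nx = 11, ny = 11, step_um = 25, colony_radius_um = 36,
                      seed = 7, axis = ax)
  expect_equal(dim(sim$mask), c(11L, 11L))
  # radius 36 um at 25 um step: center, orthogonal (25 um) and diagonal
  # (35.36 um) neighbours are inside; the next ring (50 um) is not
  expected <- matrix(FALSE, 11, 11)
  expected[5:7, 5:7] <- TRUE
  expect_identical(sim$mask, expected)

  # sub-half-step radius on an even grid: no node inside
  tiny <- simulate_map(nx = 4, ny = 4, step_um = 25, colony_radius_um = 10,
                       seed = 1, axis = ax)
  expect_false(any(tiny$mask))

  # S8 only inside: mean 470-window area larger inside than outside
  img <- band_image(sim$map, 470, 10)
  expect_gt(mean(img[sim$mask]), mean(img[!sim$mask]))
  expect_error(simulate_map(colony_radius_um = 0), "> 0")
})

test_that("kinetic profile follows a dilated logistic", {
  p <- kinetic_profile(c0 = 30, c_max = 70, t_mid = 40, rate = 0.15)
  expect_equal(profile_concentration(p, -1e6), 30)
  expect_equal(profile_concentration(p, 1e6), 70)
  # steeper at its inflection under light than under dark dilation
  d <- kinetic_profile(c0 = 30, c_max = 70, t_mid = 40, rate = 0.15,
                       light_factor = 0.5)
  delta <- 0.01
  slope_at <- function(pr, t) {
    diff(profile_concentration(pr, c(t - delta, t + delta))) / (2 * delta)
  }
  expect_gt(slope_at(p, 40 / 1), slope_at(d, 40 / 0.5))
  # dark course is the light course with time dilated by 1/light_factor
  t <- seq(0, 100, by = 5)
  expect_equal(profile_concentration(d, t / 0.5), profile_concentration(p, t))
  expect_error(kinetic_profile(c0 = 20), "25 <= c0")
  expect_error(kinetic_profile(light_factor = 0), "light_factor")
})

test_that("timecourse simulation is deterministic and follows the profile", {
  p <- kinetic_profile()
  tc1 <- simulate_timecourse(p, c(0, 40, 80), replicates = 2, noise_sd = 1,
                             seed = 5, axis = short_axis(900, 2400))
  tc2 <- simulate_timecourse(p, c(0, 40, 80), replicates = 2, noise_sd = 1,
                             seed = 5, axis = short_axis(900, 2400))
  expect_identical(lapply(tc1, function(e) e$spectra[[1L]]$intensity),
                   lapply(tc2, function(e) e$spectra[[1L]]$intensity))
  expect_equal(sapply(tc1, `[[`, "conc_true"),
               profile_concentration(p, c(0, 40, 80)))
  expect_error(simulate_timecourse(p, c(10, 5)), "nondecreasing")
})
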