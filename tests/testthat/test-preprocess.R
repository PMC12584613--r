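test_that("despiking is a no-op on smooth noiseless spectra", {
  s <- simulate_spectrum(scene_truth(default_interface_bands(50, 300, 400)))
  out <- remove_cosmic_rays(s)
  expect_length(out$spikes, 0L)
  expect_identical(out$spectrum$intensity, s$intensity)
})

test_that("an injected spike is located and repaired against pre-injection truth", {
  noise_sd <- 2
  base <- scene_truth(default_interface_bands(50), noise_sd = noise_sd, seed = 5)
  clean <- simulate_spectrum(base)
  spiked <- scene_truth(default_interface_bands(50), noise_sd = noise_sd,
                        seed = 5, spikes = list(c(500, 100 * noise_sd)))
  out <- remove_cosmic_rays(simulate_spectrum(spiked))
  expect_true(all(out$spikes %in% 499:501))
  expect_true(500 %in% out$spikes)
  expect_lt(abs(out$spectrum$intensity[500] - clean$intensity[500]),
            3 * noise_sd)

  # two adjacent spike channels are both repaired
  adj <- scene_truth(default_interface_bands(50), noise_sd = noise_sd, seed = 5,
                     spikes = list(c(500, 200), c(501, 180)))
  out2 <- remove_cosmic_rays(simulate_spectrum(adj))
  expect_true(all(c(500, 501) %in% out2$spikes))
  expect_lt(abs(out2$spectrum$intensity[500] - clean$intensity[500]),
            3 * noise_sd)
  expect_lt(abs(out2$spectrum$intensity[501] - clean$intensity[501]),
            3 * noise_sd)
})

test_that("despiking validates its arguments", {
  s <- raman_spectrum(1:16, rep(1, 16))
  expect_error(remove_cosmic_rays(s, window = 4), "odd")
  expect_error(remove_cosmic_rays(s, window = 17), "shorter than window")
  expect_error(remove_cosmic_rays(s, z_thresh = 0), "> 0")
})

test_that("baseline decomposition is exactly additive on any input", {
  truth <- scene_truth(default_interface_bands(50, 200, 100),
                       baseline_coeffs = c(100, -50, 80), noise_sd = 5, seed = 3)
  s <- simulate_spectrum(truth)
  for (meth in c("als", "polynomial")) {
    res <- correct_baseline(s, meth)
    # the decomposition is defined by subtraction, so this is bit-exact
    expect_identical(s$intensity - res$baseline, res$corrected$intensity)
    expect_equal(res$corrected$intensity + res$baseline, s$intensity,
                 tolerance = 1e-12)
  }
})

test_that("baseline estimators recover synthetic truth", {
  # zero-baseline noiseless spectrum: baseline below 1e-3 of peak height
  s <- simulate_spectrum(scene_truth(default_interface_bands(50)))
  peak_h <- max(s$intensity)
  expect_lt(max(abs(correct_baseline(s, "als")$baseline)), 1e-3 * peak_h)

  # known quadratic baseline under an isolated band: within 1% of band height
  tr <- scene_truth(list(raman_band("b", 980, 8, 1000)),
                    baseline_coeffs = c(50, 30, -40))
  s2 <- simulate_spectrum(tr)
  u <- (s2$wavenumber - 200) / 2300
  true_bl <- 50 + 30 * u - 40 * u^2
  for (meth in c("als", "polynomial")) {
    est <- correct_baseline(s2, meth, degree = 2)$baseline
    expect_lt(max(abs(est - true_bl)), 0.01 * 1000)
  }
  expect_error(correct_baseline(s, "als", p = 1.5), "p must be")
  expect_error(correct_baseline(s, "polynomial", degree = 9), "<= 6")
})

test_that("silicon wavenumber calibration recovers and removes axis offsets", {
  si_exact <- simulate_spectrum(scene_truth(list(raman_band("Si", 520, 6, 2000))))
  expect_equal(calibrate_wavenumber(si_exact, si_exact)$offset, 0,
               tolerance = 1e-6)

  si_off <- simulate_spectrum(scene_truth(list(raman_band("Si", 523, 6, 2000))))
  cal <- calibrate_wavenumber(si_off, si_off)
  expect_equal(cal$offset, 3, tolerance = 1e-6)
  refit <- fit_peaks(cal$spectrum, c(470, 570), 1)
  expect_equal(refit$peaks$center[1L], 520, tolerance = 1e-6)

  # idempotence: a corrected spectrum yields offset ~0
  cal2 <- calibrate_wavenumber(cal$spectrum, cal$spectrum)
  expect_equal(cal2$offset, 0, tolerance = 1e-6)

  flat <- simulate_spectrum(scene_truth(baseline_coeffs = 0))
  expect_error(calibrate_wavenumber(flat, flat), "calibration failed")
})

test_that("replicate averaging matches elementwise recomputation", {
  ax <- short_axis()
  a <- raman_spectrum(ax, rep(0, length(ax)))
  b <- raman_spectrum(ax, rep(2, length(ax)))
  res <- average_spectra(list(a, b))
  expect_true(all(res$mean$intensity == 1))
  expect_true(all(abs(res$sd - sqrt(2)) < 1e-12))

  same <- average_spectra(list(a, a, a))
  expect_identical(same$mean$intensity, a$intensity)
  expect_true(all(same$sd == 0))
  expect_equal(same$mean$meta$n_averaged, 3L)

  reps <- lapply(1:3, function(i) {
    simulate_spectrum(scene_truth(list(raman_band("b", 980, 8, 1000)),
                                  noise_sd = 2, seed = 42 + i), axis = ax)
  })
  res2 <- average_spectra(reps)
  mat <- sapply(reps, `[[`, "intensity")
  brute_mean <- sapply(seq_len(nrow(mat)), function(i) sum(mat[i, ]) / 3)
  brute_sd <- sapply(seq_len(nrow(mat)), function(i) {
    sqrt(sum((mat[i, ] - brute_mean[i])^2) / 2)
  })
  expect_equal(res2$mean$intensity, brute_mean)
  expect_equal(res2$sd, brute_sd)

  short <- raman_spectrum(ax + 1, rep(0, length(ax)))
  expect_error(average_spectra(list(a, short)), "identical wavenumber axes")
  expect_error(average_spectra(list(a)), ">= 2")
})
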