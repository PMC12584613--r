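# shared fixtures, built in code

# calibration model on exact points of the default generator line
exact_calibration <- function() {
  concs <- c(25, 37.5, 50, 62.5, 75)
  fit_calibration(data.frame(conc = concs, ratio = 0.01802 * concs - 0.04239))
}

# short strictly-increasing axis around one band, for cheap fits
short_axis <- function(lo = 900, hi = 1060) seq(lo, hi, by = 1)

# one isolated noiseless Gaussian on the default axis
isolated_band_spectrum <- function(center = 980, fwhm = 8, height = 1000) {
  simulate_spectrum(scene_truth(list(raman_band("b", center, fwhm, height))))
}
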