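## Synthetic gas-solid interface scenes with exact ground truth.
##
## No raw spectra are deposited for this measurement system, so validation
## runs entirely on generated data whose band areas, baselines, noise and
## kinetics are known exactly. The generator mirrors the model the analysis
## assumes: Gaussian bands, polynomial baseline, additive i.i.d. Gaussian
## noise, single-channel cosmic-ray spikes.

# analytic area of a unit-height Gaussian of unit FWHM
GAUSS_AREA_FACTOR <- sqrt(pi / (4 * log(2)))

# printed calibration line the generator reproduces by construction:
# area ratio sulfate/N2 = slope * C + intercept, valid 25-75 mmol/L
DEFAULT_CALIB_SLOPE <- 0.01802
DEFAULT_CALIB_INTERCEPT <- -0.04239
DEFAULT_CALIB_RANGE <- c(25, 75)

# default wavenumber axis: 200-2500 cm^-1 at 1 cm^-1 spacing (the instrument
# resolution is 3 cm^-1; 3x oversampling keeps Gaussian fits well-conditioned)
#' Default wavenumber axis for synthetic spectra
#' @return Numeric vector, 200 to 2500 cm^-1 in 1 cm^-1 steps.
#' @export
default_axis <- function() seq(200, 2500, by = 1)

# fixed internal-standard amplitude: headspace N2 is held at constant
# pressure (0.3 MPa), so its band is constant by design
N2_CENTER <- 2332; N2_FWHM <- 10; N2_HEIGHT <- 1000
SULFATE_CENTER <- 980; SULFATE_FWHM <- 8
S8_CENTER <- 470; S8_FWHM <- 10
CAROT_CENTERS <- c(1005, 1157, 1523)
CAROT_FWHMS <- c(12, 12, 14)
CAROT_REL_HEIGHTS <- c(0.35, 0.80, 1.00)

#' Analytic area of a Gaussian band
#'
#' @param height Peak height (CCD counts).
#' @param fwhm Full width at half maximum (cm^-1).
#' @return Area `height * fwhm * sqrt(pi / (4 log 2))` in counts * cm^-1.
#' @export
gaussian_area <- function(height, fwhm) height * fwhm * GAUSS_AREA_FACTOR

#' Define a Gaussian band
#'
#' @param name Band label.
#' @param center Band center (cm^-1).
#' @param fwhm Full width at half maximum (cm^-1), > 0.
#' @param height Peak height (CCD counts), >= 0.
#' @return A `raman_band` list.
#' @export
raman_band <- function(name, center, fwhm, height) {
  if (!is.finite(fwhm) || fwhm <= 0) stop("fwhm must be > 0", call. = FALSE)
  if (!is.finite(height) || height < 0) stop("height must be >= 0", call. = FALSE)
  structure(list(name = name, center = as.double(center),
                 fwhm = as.double(fwhm), height = as.double(height)),
            class = "raman_band")
}

band_profile <- function(axis, band) {
  band$height * exp(-4 * log(2) * (axis - band$center)^2 / band$fwhm^2)
}

#' Define the ground truth of a synthetic scene
#'
#' @param bands List of [raman_band()] objects; centers must lie inside the
#'   axis used for simulation.
#' @param baseline_coeffs Polynomial baseline coefficients (increasing
#'   order), evaluated in the scaled coordinate `u = (wn - min) / span` so
#'   the polynomial is well-conditioned on any axis. A single coefficient is
#'   a constant offset.
#' @param noise_sd Additive Gaussian noise SD (CCD counts), >= 0.
#' @param spikes List of `c(channel, magnitude)` cosmic-ray spikes; channel
#'   indices must lie within the axis.
#' @param seed Integer seed making the scene reproducible.
#' @return A `scene_truth` list.
#' @export
scene_truth <- function(bands = list(), baseline_coeffs = 0,
                        noise_sd = 0, spikes = list(), seed = 1L) {
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(bands = bands, baseline_coeffs = as.double(baseline_coeffs),
                 noise_sd = as.double(noise_sd), spikes = spikes,
                 seed = as.integer(seed)),
            class = "scene_truth")
}

# evaluate expr with a local RNG stream; global .Random.seed is untouched
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic substream seed, kept inside 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483629)
}

#' Simulate one spectrum from a scene truth
#'
#' Intensity is the sum of the Gaussian bands
#' `height * exp(-4 log(2) (wn - center)^2 / fwhm^2)`, the polynomial
#' baseline, i.i.d. Gaussian noise of SD `noise_sd`, and the cosmic-ray
#' spikes. Deterministic given `truth$seed`; the global RNG state is left
#' untouched.
#'
#' @param truth A [scene_truth()].
#' @param axis Strictly increasing wavenumber axis (cm^-1); default
#'   [default_axis()].
#' @return A [raman_spectrum()] with the truth seed recorded in metadata.
#' @export
simulate_spectrum <- function(truth, axis = default_axis()) {
  stopifnot(inherits(truth, "scene_truth"))
  axis <- as.double(axis)
  if (any(diff(axis) <= 0)) stop("axis must be strictly increasing", call. = FALSE)
  for (b in truth$bands) {
    if (b$center < min(axis) || b$center > max(axis)) {
      stop(sprintf("band '%s' center %.1f outside axis span", b$name, b$center),
           call. = FALSE)
    }
  }
  u <- (axis - axis[1L]) / (axis[length(axis)] - axis[1L])
  intensity <- rep(0, length(axis))
  for (b in truth$bands) intensity <- intensity + band_profile(axis, b)
  for (k in seq_along(truth$baseline_coeffs)) {
    intensity <- intensity + truth$baseline_coeffs[k] * u^(k - 1L)
  }
  if (truth$noise_sd > 0) {
    intensity <- intensity +
      with_seed(truth$seed, stats::rnorm(length(axis), 0, truth$noise_sd))
  }
  for (sp in truth$spikes) {
    ch <- as.integer(sp[1L])
    if (ch < 1L || ch > length(axis)) {
      stop(sprintf("spike channel %d outside axis bounds", ch), call. = FALSE)
    }
    intensity[ch] <- intensity[ch] + sp[2L]
  }
  raman_spectrum(axis, intensity,
                 meta = list(synthetic = TRUE, seed = truth$seed,
                             noise_sd = truth$noise_sd))
}

#' Default band table of the gas-solid interface
#'
#' Builds the bands observed at the nitrogen-pressurized interface of the
#' solid medium: the N2 internal standard at 2332 cm^-1 (fixed height -- the
#' headspace pressure is held constant), sulfate S-O stretch at 980 cm^-1
#' whose area is scaled so that the sulfate/N2 area ratio equals
#' `0.01802 * C - 0.04239` exactly, the S8 S-S band at 470 cm^-1, and three
#' carotenoid bands at 1005, 1157 and 1523 cm^-1. The 1005 cm^-1 companion
#' deliberately overlaps the sulfate fitting window so that deconvolution is
#' exercised; only the 1523 cm^-1 polyene C=C band is used for imaging.
#'
#' @param sulfate_conc Sulfate concentration in mmol/L, within 0 to 100.
#'   Concentrations low enough that the calibration line predicts a
#'   non-positive ratio yield no sulfate band.
#' @param carotenoid_level Height (CCD counts) of the 1523 cm^-1 band; the
#'   companions scale proportionally. >= 0.
#' @param s8_level Height (CCD counts) of the 470 cm^-1 band. >= 0.
#' @return List of [raman_band()] objects.
#' @export
default_interface_bands <- function(sulfate_conc, carotenoid_level = 0,
                                    s8_level = 0) {
  if (!is.finite(sulfate_conc) || sulfate_conc < 0 || sulfate_conc > 100) {
    stop("sulfate_conc must be within [0, 100] mmol/L", call. = FALSE)
  }
  if (carotenoid_level < 0 || s8_level < 0) {
    stop("band levels must be >= 0", call. = FALSE)
  }
  bands <- list(raman_band("N2", N2_CENTER, N2_FWHM, N2_HEIGHT))
  ratio <- DEFAULT_CALIB_SLOPE * sulfate_conc + DEFAULT_CALIB_INTERCEPT
  if (ratio > 0) {
    a_n2 <- gaussian_area(N2_HEIGHT, N2_FWHM)
    h_so4 <- ratio * a_n2 / (SULFATE_FWHM * GAUSS_AREA_FACTOR)
    bands <- c(bands, list(raman_band("sulfate", SULFATE_CENTER, SULFATE_FWHM, h_so4)))
  }
  if (s8_level > 0) {
    bands <- c(bands, list(raman_band("S8", S8_CENTER, S8_FWHM, s8_level)))
  }
  if (carotenoid_level > 0) {
    for (i in seq_along(CAROT_CENTERS)) {
      bands <- c(bands, list(raman_band(
        c("carotenoid-overlap", "carotenoid-1157", "carotenoid")[i],
        CAROT_CENTERS[i], CAROT_FWHMS[i],
        carotenoid_level * CAROT_REL_HEIGHTS[i])))
    }
  }
  bands
}

#' Generator noise defaults
#'
#' Per-channel Gaussian noise SDs (CCD counts) used by the calibration
#' generator. `DEFAULT_CALIB_NOISE_SD` yields about 0.5% relative error on
#' the fitted sulfate band area at mid-range concentration (calibrated once
#' by Monte Carlo against the default band table; see the methods
#' vignette); `LOW_NOISE_CALIB_SD` scales that to about 0.1%.
#' @export
DEFAULT_CALIB_NOISE_SD <- 4

#' @rdname DEFAULT_CALIB_NOISE_SD
#' @export
LOW_NOISE_CALIB_SD <- 0.8

#' Simulate a calibration series
#'
#' One spectrum per (concentration, replicate) built from the default
#' interface band table, so the true sulfate/N2 area ratio at concentration C
#' is exactly `0.01802 * C - 0.04239`. Replicate seeds derive
#' deterministically from the master seed. Concentrations outside the
#' 25-75 mmol/L validity range are permitted but flagged in the spectrum
#' metadata (`out_of_range = TRUE`).
#'
#' @param concs Concentrations in mmol/L.
#' @param replicates Replicates per concentration, >= 1 (default 3, matching
#'   acquisition at >= 3 distinct interface positions).
#' @param noise_sd Per-channel Gaussian noise SD in CCD counts. The default
#'   gives about 0.5% relative error on fitted band areas.
#' @param seed Master seed.
#' @param baseline_coeffs Baseline polynomial passed to every scene.
#' @param axis Wavenumber axis.
#' @return A list with one element per spectrum: `list(conc, replicate,
#'   spectrum)`.
#' @export
simulate_calibration_series <- function(concs = c(25, 37.5, 50, 62.5, 75),
                                        replicates = 3,
                                        noise_sd = DEFAULT_CALIB_NOISE_SD,
                                        seed = 1L,
                                        baseline_coeffs = 0,
                                        axis = default_axis()) {
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  out <- vector("list", length(concs) * replicates)
  k <- 0L
  for (i in seq_along(concs)) {
    for (r in seq_len(replicates)) {
      k <- k + 1L
      truth <- scene_truth(default_interface_bands(concs[i]),
                           baseline_coeffs = baseline_coeffs,
                           noise_sd = noise_sd,
                           seed = derive_seed(seed, k))
      sp <- simulate_spectrum(truth, axis)
      sp$meta$conc_mmol_L <- concs[i]
      sp$meta$replicate <- r
      if (concs[i] < DEFAULT_CALIB_RANGE[1L] || concs[i] > DEFAULT_CALIB_RANGE[2L]) {
        sp$meta$out_of_range <- TRUE
      }
      out[[k]] <- list(conc = concs[i], replicate = r, spectrum = sp)
    }
  }
  out
}

#' Simulate a colony spectral map
#'
#' A rectangular grid with a central circular colony: nodes within
#' `colony_radius_um` of the grid center take the `inside` band levels,
#' the rest the `outside` levels. Returns the map together with the boolean
#' disc-membership mask, which downstream imaging tests use as ground truth.
#'
#' @param nx,ny Grid dimensions (nodes).
#' @param step_um Grid step in um (> 0; area scans typically use 20-30 um).
#' @param colony_radius_um Colony disc radius in um, > 0.
#' @param inside,outside Named lists with elements `sulfate_conc`,
#'   `carotenoid_level`, `s8_level` (missing elements default to 0).
#' @param noise_sd Per-channel noise SD.
#' @param seed Master seed; each node gets a derived seed.
#' @param axis Shared wavenumber axis.
#' @return List with elements `map` ([raman_map()]) and `mask` (ny x nx
#'   logical matrix, TRUE inside the colony disc).
#' @export
simulate_map <- function(nx = 11, ny = 11, step_um = 25, colony_radius_um,
                         inside = list(sulfate_conc = 50, s8_level = 400,
                                       carotenoid_level = 300),
                         outside = list(sulfate_conc = 50),
                         noise_sd = 0, seed = 1L, axis = default_axis()) {
  if (colony_radius_um <= 0) stop("colony_radius_um must be > 0", call. = FALSE)
  xs <- (seq_len(nx) - 1) * step_um
  ys <- (seq_len(ny) - 1) * step_um
  half_span <- c((nx - 1) / 2, (ny - 1) / 2) * step_um
  if (colony_radius_um > min(half_span) && min(half_span) > 0) {
    stop("colony disc does not fit inside the grid", call. = FALSE)
  }
  cx <- mean(range(xs)); cy <- mean(range(ys))
  levels_of <- function(l) {
    list(sulfate_conc = l$sulfate_conc %||% 0,
         carotenoid_level = l$carotenoid_level %||% 0,
         s8_level = l$s8_level %||% 0)
  }
  li <- levels_of(inside); lo <- levels_of(outside)
  cube <- array(0, dim = c(ny, nx, length(axis)))
  mask <- matrix(FALSE, ny, nx)
  k <- 0L
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      k <- k + 1L
      inside_disc <- sqrt((xs[ix] - cx)^2 + (ys[iy] - cy)^2) <= colony_radius_um
      mask[iy, ix] <- inside_disc
      lv <- if (inside_disc) li else lo
      truth <- scene_truth(
        default_interface_bands(lv$sulfate_conc, lv$carotenoid_level, lv$s8_level),
        noise_sd = noise_sd, seed = derive_seed(seed, k))
      cube[iy, ix, ] <- simulate_spectrum(truth, axis)$intensity
    }
  }
  list(map = raman_map(xs, ys, axis, cube,
                       meta = list(seed = seed, colony_radius_um = colony_radius_um)),
       mask = mask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Define a logistic kinetic profile for sulfate production
#'
#' Sulfate released by thiosulfate disproportionation follows the observed
#' three-phase course (slow initial rise, rapid mid-incubation production,
#' late plateau); a logistic captures this:
#' `c(t) = c0 + (c_max - c0) / (1 + exp(-rate * (light_factor * t - t_mid)))`.
#' Darkness acts as a dilation of the metabolic time axis: with
#' `light_factor < 1` the effective rate is `rate * light_factor` and the
#' inflection is delayed to `t_mid / light_factor`, so the whole synthesis
#' cycle is both slowed and prolonged relative to the light condition — a
#' dark course is exactly the light course with time stretched by
#' `1 / light_factor`.
#'
#' @param c0 Initial sulfate concentration (mmol/L), 25 <= c0 < c_max.
#' @param c_max Plateau concentration (mmol/L), <= 75.
#' @param t_mid Inflection position on the light-condition time axis (h).
#' @param rate Logistic rate (1/h), > 0.
#' @param light_factor Time-dilation factor; 1 under natural light, < 1 in
#'   the dark (must be in (0, 1]).
#' @return A `kinetic_profile` list.
#' @export
kinetic_profile <- function(c0 = 30, c_max = 70, t_mid = 40, rate = 0.15,
                            light_factor = 1) {
  if (!(c0 >= 25 && c0 < c_max && c_max <= 75)) {
    stop("need 25 <= c0 < c_max <= 75 mmol/L", call. = FALSE)
  }
  if (rate <= 0) stop("rate must be > 0", call. = FALSE)
  if (!(light_factor > 0 && light_factor <= 1)) {
    stop("light_factor must be in (0, 1]", call. = FALSE)
  }
  structure(list(c0 = c0, c_max = c_max, t_mid = t_mid, rate = rate,
                 light_factor = light_factor),
            class = "kinetic_profile")
}

#' Evaluate a kinetic profile
#' @param profile A [kinetic_profile()].
#' @param times Times (h).
#' @return Sulfate concentrations (mmol/L).
#' @export
profile_concentration <- function(profile, times) {
  stopifnot(inherits(profile, "kinetic_profile"))
  with(profile, c0 + (c_max - c0) /
         (1 + exp(-rate * (light_factor * times - t_mid))))
}

#' Simulate a quantification time course
#'
#' At each time the sulfate concentration follows the logistic profile and
#' `replicates` interface spectra are generated via
#' [default_interface_bands()].
#'
#' @param profile A [kinetic_profile()].
#' @param times Nondecreasing acquisition times (h).
#' @param replicates Spectra per time point.
#' @param noise_sd Per-channel noise SD.
#' @param seed Master seed.
#' @param axis Wavenumber axis.
#' @return List with one element per time: `list(time, conc_true, spectra)`.
#' @export
simulate_timecourse <- function(profile, times, replicates = 3,
                                noise_sd = DEFAULT_CALIB_NOISE_SD, seed = 1L,
                                axis = default_axis()) {
  if (any(diff(times) < 0)) stop("times must be nondecreasing", call. = FALSE)
  concs <- profile_concentration(profile, times)
  out <- vector("list", length(times))
  k <- 0L
  for (i in seq_along(times)) {
    spectra <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      k <- k + 1L
      truth <- scene_truth(default_interface_bands(concs[i]),
                           noise_sd = noise_sd, seed = derive_seed(seed, k))
      sp <- simulate_spectrum(truth, axis)
      sp$meta$time_h <- times[i]
      spectra[[r]] <- sp
    }
    out[[i]] <- list(time = times[i], conc_true = concs[i], spectra = spectra)
  }
  out
}
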