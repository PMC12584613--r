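#' Construct a Raman spectrum
#'
#' A `raman_spectrum` holds one wavenumber-indexed intensity trace plus an
#' acquisition-metadata record. Intensities are in CCD counts (stored as
#' doubles: averaged spectra are non-integer), the axis in Raman shift
#' (cm^-1).
#'
#' @param wavenumber Numeric vector of Raman shifts (cm^-1), strictly
#'   increasing, length >= 16.
#' @param intensity Numeric vector of intensities (CCD counts), same length,
#'   all finite.
#' @param meta Named list of acquisition metadata (e.g. `label`,
#'   `position_um`, `integration_time_s`, `accumulations`, `laser_power_mW`,
#'   `timestamp_h`). May be empty.
#' @return An object of class `raman_spectrum`: a list with elements
#'   `wavenumber`, `intensity`, `meta`.
#' @examples
#' wn <- seq(200, 2500)
#' s <- raman_spectrum(wn, exp(-((wn - 980) / 10)^2))
#' s
#' @export
raman_spectrum <- function(wavenumber, intensity, meta = list()) {
  wavenumber <- as.double(wavenumber)
  intensity <- as.double(intensity)
  if (length(wavenumber) != length(intensity)) {
    stop("wavenumber and intensity must have equal length", call. = FALSE)
  }
  if (length(wavenumber) < 16L) {
    stop("a spectrum needs at least 16 channels", call. = FALSE)
  }
  dw <- diff(wavenumber)
  if (any(!is.finite(wavenumber))) {
    stop("non-finite wavenumber values", call. = FALSE)
  }
  if (any(dw <= 0)) {
    idx <- which(dw <= 0)[1L]
    stop(sprintf("wavenumber axis not strictly increasing at index %d", idx + 1L),
         call. = FALSE)
  }
  if (any(!is.finite(intensity))) {
    idx <- which(!is.finite(intensity))[1L]
    stop(sprintf("non-finite intensity at index %d", idx), call. = FALSE)
  }
  if (!is.list(meta)) stop("meta must be a list", call. = FALSE)
  structure(list(wavenumber = wavenumber, intensity = intensity, meta = meta),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("Raman spectrum: %d channels, %.1f-%.1f cm^-1\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  cat(sprintf("  intensity range: %.3g to %.3g CCD counts\n",
              min(x$intensity), max(x$intensity)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.raman_spectrum <- function(x, ...) {
  data.frame(wavenumber = x$wavenumber, intensity = x$intensity)
}

#' Number of channels of a spectrum
#' @param x A `raman_spectrum`.
#' @return Integer channel count.
#' @export
n_channels <- function(x) length(x$wavenumber)

#' Construct a rectangular Raman spectral map
#'
#' A `raman_map` is a rectangular grid of spectra sharing one wavenumber axis,
#' as produced by confocal area scans (step size typically 20-30 um). Spectra
#' are stored row-major by ascending y then x; this ordering is part of the
#' on-disk contract so imaging output is reproducible bit-for-bit.
#'
#' @param xs,ys Sorted unique grid coordinates (um) with constant step.
#' @param wavenumber Shared wavenumber axis (cm^-1), strictly increasing.
#' @param cube Numeric array of intensities, dim `c(length(ys), length(xs),
#'   length(wavenumber))` (row index = y, column index = x).
#' @param meta Named list of map-level metadata.
#' @return An object of class `raman_map`.
#' @export
raman_map <- function(xs, ys, wavenumber, cube, meta = list()) {
  xs <- as.double(xs); ys <- as.double(ys)
  if (length(xs) < 1L || length(ys) < 1L) stop("empty grid", call. = FALSE)
  check_step <- function(v, nm) {
    if (length(v) > 1L) {
      st <- diff(v)
      if (any(st <= 0)) stop(sprintf("%s not strictly increasing", nm), call. = FALSE)
      if (diff(range(st)) > 1e-9 * max(st)) {
        stop(sprintf("%s grid step not constant", nm), call. = FALSE)
      }
    }
  }
  check_step(xs, "x"); check_step(ys, "y")
  if (any(diff(wavenumber) <= 0)) {
    stop("shared wavenumber axis not strictly increasing", call. = FALSE)
  }
  cube <- array(as.double(cube), dim = c(length(ys), length(xs), length(wavenumber)))
  if (any(!is.finite(cube))) stop("non-finite intensity in map", call. = FALSE)
  structure(list(xs = xs, ys = ys, wavenumber = as.double(wavenumber),
                 cube = cube, meta = meta),
            class = "raman_map")
}

#' @export
print.raman_map <- function(x, ...) {
  cat(sprintf("Raman map: %d x %d nodes, %d channels, %.1f-%.1f cm^-1\n",
              length(x$xs), length(x$ys), length(x$wavenumber),
              min(x$wavenumber), max(x$wavenumber)))
  if (length(x$xs) > 1L) cat(sprintf("  step: %.3g um\n", x$xs[2] - x$xs[1]))
  invisible(x)
}

#' Extract one spectrum from a map node
#' @param map A `raman_map`.
#' @param ix,iy Column (x) and row (y) indices, 1-based.
#' @return A `raman_spectrum`.
#' @export
map_spectrum <- function(map, ix, iy) {
  stopifnot(inherits(map, "raman_map"))
  raman_spectrum(map$wavenumber, map$cube[iy, ix, ],
                 meta = list(x_um = map$xs[ix], y_um = map$ys[iy]))
}
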