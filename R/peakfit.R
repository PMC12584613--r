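## Windowed Gaussian peak fitting: band position, width, height, area, with
## multi-component deconvolution of overlapping bands (sulfate 980 cm^-1 vs
## the carotenoid companion near 1005 cm^-1).

#' Fit Gaussian peaks in a spectral window
#'
#' Nonlinear least squares of a sum of `n_components` Gaussians,
#' `sum_j h_j exp(-4 log(2) (wn - c_j)^2 / w_j^2)`, to the window
#' `[lo, hi]`. A local linear baseline (the chord through the window
#' endpoints) is removed before fitting, even after global baseline
#' correction — the global step cannot be assumed perfect. Parameters are
#' bounded (centers inside the window, FWHM between twice the channel
#' spacing and the window width, heights nonnegative) to prevent component
#' swapping during deconvolution. Initialization comes from `init` when
#' given, otherwise from the `n_components` largest local maxima; up to
#' `restarts` Levenberg-Marquardt restarts with seeded, jittered starting
#' values guard against the non-convexity of multi-component fits.
#'
#' @param s A [raman_spectrum()].
#' @param window Numeric `c(lo, hi)` in cm^-1; must contain >= 8 channels.
#' @param n_components Number of Gaussians, 1 to 5.
#' @param init Optional list of [raman_band()] starting values (length
#'   `n_components`).
#' @param local_baseline Remove the endpoint chord before fitting
#'   (default TRUE).
#' @param restarts Maximum jittered restarts on non-convergence (default 5).
#' @param seed Seed for the restart jitter.
#' @return An object of class `raman_peakfit`: `peaks` (data.frame sorted by
#'   center with columns center, fwhm, height, area and their standard
#'   errors), `window`, `residual_sd`, `converged`, `fitted`, `data`.
#' @export
fit_peaks <- function(s, window, n_components = 1, init = NULL,
                      local_baseline = TRUE, restarts = 5, seed = 1L) {
  stopifnot(inherits(s, "raman_spectrum"))
  if (length(window) != 2L || window[1L] >= window[2L]) {
    stop("window must be c(lo, hi) with lo < hi", call. = FALSE)
  }
  if (n_components < 1 || n_components > 5) {
    stop("n_components must be between 1 and 5", call. = FALSE)
  }
  sel <- s$wavenumber >= window[1L] & s$wavenumber <= window[2L]
  if (sum(sel) < 8L) stop("window contains fewer than 8 channels", call. = FALSE)
  x <- s$wavenumber[sel]
  y <- s$intensity[sel]
  if (local_baseline) {
    chord <- y[1L] + (y[length(y)] - y[1L]) * (x - x[1L]) / (x[length(x)] - x[1L])
    y <- y - chord
  }
  spacing <- stats::median(diff(x))
  width_lo <- 2 * spacing
  width_hi <- diff(window)

  if (!is.null(init)) {
    if (length(init) != n_components) {
      stop("init must supply one band per component", call. = FALSE)
    }
    starts <- t(vapply(init, function(b) c(b$height, b$center, b$fwhm),
                       numeric(3)))
  } else {
    starts <- init_from_maxima(x, y, n_components)
  }

  k <- n_components
  par_names <- as.vector(t(outer(c("h", "c", "w"), seq_len(k), paste0)))
  gauss_sum <- function(pars) {
    out <- numeric(length(x))
    for (j in seq_len(k)) {
      out <- out + pars[3L * j - 2L] *
        exp(-4 * log(2) * (x - pars[3L * j - 1L])^2 / pars[3L * j]^2)
    }
    out
  }
  lower <- rep(c(0, window[1L], width_lo), k)
  upper <- rep(c(2 * max(abs(y)) + .Machine$double.eps, window[2L], width_hi), k)
  # starts rows are (h, c, w) per component; flatten interleaved h,c,w
  start0 <- pmin(pmax(as.vector(t(starts)), lower), upper)

  resid_fn <- function(pars) y - gauss_sum(pars)
  best <- NULL
  best_ss <- Inf
  converged <- FALSE
  jitters <- with_seed(derive_seed(seed, 211L),
                       matrix(stats::runif(restarts * 3L * k, -1, 1),
                              nrow = restarts))
  for (attempt in 0:restarts) {
    st <- if (attempt == 0L) start0 else {
      jit <- jitters[attempt, ]
      pmin(pmax(start0 * (1 + 0.2 * jit) +
                  rep(c(0, 2, 0), k) * jit, lower), upper)
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(resid_fn(fit$par)^2)
    ok <- fit$info %in% 1:4
    if (ss < best_ss) { best <- fit; best_ss <- ss }
    if (ok) { converged <- TRUE; break }
  }
  if (is.null(best)) {
    stop("peak fit failed to converge; no valid evaluation", call. = FALSE)
  }
  if (!converged) {
    stop(sprintf(
      "peak fit did not converge after %d restarts (best residual SS %.4g)",
      restarts, best_ss), call. = FALSE)
  }

  pars <- best$par
  dof <- max(1L, length(y) - 3L * k)
  residual_sd <- sqrt(best_ss / dof)
  # covariance from the analytic Jacobian of the Gaussian sum
  J <- matrix(0, length(x), 3L * k)
  for (j in seq_len(k)) {
    h <- pars[3L * j - 2L]; cc <- pars[3L * j - 1L]; w <- pars[3L * j]
    e <- exp(-4 * log(2) * (x - cc)^2 / w^2)
    J[, 3L * j - 2L] <- e
    J[, 3L * j - 1L] <- h * e * 8 * log(2) * (x - cc) / w^2
    J[, 3L * j]      <- h * e * 8 * log(2) * (x - cc)^2 / w^3
  }
  vc <- tryCatch((best_ss / dof) * solve(crossprod(J)),
                 error = function(e) matrix(NA_real_, 3L * k, 3L * k))

  peaks <- data.frame(center = pars[seq(2, 3 * k, by = 3)],
                      fwhm = pars[seq(3, 3 * k, by = 3)],
                      height = pars[seq(1, 3 * k, by = 3)])
  peaks$area <- gaussian_area(peaks$height, peaks$fwhm)
  se <- sqrt(pmax(diag(vc), 0))
  peaks$se_center <- se[seq(2, 3 * k, by = 3)]
  peaks$se_fwhm <- se[seq(3, 3 * k, by = 3)]
  peaks$se_height <- se[seq(1, 3 * k, by = 3)]
  # delta method for the analytic area h * w * K
  peaks$se_area <- vapply(seq_len(k), function(j) {
    ih <- 3L * j - 2L; iw <- 3L * j
    g <- c(GAUSS_AREA_FACTOR * peaks$fwhm[j], GAUSS_AREA_FACTOR * peaks$height[j])
    v <- vc[c(ih, iw), c(ih, iw)]
    if (any(is.na(v))) return(NA_real_)
    sqrt(max(0, drop(t(g) %*% v %*% g)))
  }, numeric(1))
  ord <- order(peaks$center)
  peaks <- peaks[ord, , drop = FALSE]
  rownames(peaks) <- NULL

  structure(list(peaks = peaks, window = window, residual_sd = residual_sd,
                 converged = converged, n_components = k,
                 fitted = gauss_sum(pars),
                 data = data.frame(wavenumber = x, intensity = y)),
            class = "raman_peakfit")
}

# starting values from the n largest local maxima of the window
init_from_maxima <- function(x, y, k) {
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  cand <- which(is_max)
  if (!length(cand) && k == 1L) cand <- which.max(y)
  if (length(cand) < k) {
    stop(sprintf(
      "initialization error: %d component(s) requested but only %d local maxima; supply init",
      k, length(cand)), call. = FALSE)
  }
  cand <- cand[order(y[cand], decreasing = TRUE)][seq_len(k)]
  span <- diff(range(x))
  t(vapply(cand, function(i) {
    h <- max(y[i], .Machine$double.eps)
    # half-max crossing distance as a width guess
    above <- y >= h / 2
    lo <- i; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
    hi <- i; while (hi < length(y) && above[hi + 1L]) hi <- hi + 1L
    w <- max(x[hi] - x[lo], span / 20)
    c(h, x[i], min(w, span))
  }, numeric(3)))
}

#' @export
print.raman_peakfit <- function(x, digits = 4, ...) {
  cat(sprintf("Gaussian peak fit: %d component(s) in %.1f-%.1f cm^-1\n",
              x$n_components, x$window[1L], x$window[2L]))
  print(format(x$peaks[c("center", "fwhm", "height", "area")], digits = digits))
  cat(sprintf("residual SD: %.4g CCD counts\n", x$residual_sd))
  invisible(x)
}

#' @export
coef.raman_peakfit <- function(object, ...) {
  as.matrix(object$peaks[c("center", "fwhm", "height", "area")])
}

#' @export
summary.raman_peakfit <- function(object, ...) {
  structure(list(peaks = object$peaks, window = object$window,
                 residual_sd = object$residual_sd,
                 n_points = nrow(object$data)),
            class = "summary.raman_peakfit")
}

#' @export
print.summary.raman_peakfit <- function(x, ...) {
  cat(sprintf("Gaussian peak fit over %d channels in %.1f-%.1f cm^-1\n",
              x$n_points, x$window[1L], x$window[2L]))
  print(x$peaks)
  cat(sprintf("residual SD: %.4g CCD counts\n", x$residual_sd))
  invisible(x)
}

#' @export
fitted.raman_peakfit <- function(object, ...) object$fitted

#' @export
residuals.raman_peakfit <- function(object, ...) {
  object$data$intensity - object$fitted
}

#' @export
plot.raman_peakfit <- function(x, ...) {
  graphics::plot(x$data$wavenumber, x$data$intensity,
                 xlab = expression(paste("Raman shift (", cm^-1, ")")),
                 ylab = "Intensity (CCD counts)", pch = 16, cex = 0.5, ...)
  graphics::lines(x$data$wavenumber, x$fitted, col = "red3", lwd = 2)
  for (j in seq_len(nrow(x$peaks))) {
    graphics::lines(x$data$wavenumber,
                    x$peaks$height[j] * exp(-4 * log(2) *
                      (x$data$wavenumber - x$peaks$center[j])^2 / x$peaks$fwhm[j]^2),
                    col = "steelblue", lty = 2)
  }
  invisible(x)
}

#' Numeric band area by trapezoidal integration
#'
#' Trapezoidal integral of the (optionally chord-subtracted) intensity over
#' a window. Serves as the model-free cross-check of the analytic Gaussian
#' areas returned by [fit_peaks()].
#'
#' @param s A [raman_spectrum()].
#' @param window Numeric `c(lo, hi)` in cm^-1 within the axis.
#' @param local_baseline Subtract the chord through the window endpoints
#'   (default TRUE).
#' @return Area (CCD counts * cm^-1).
#' @export
peak_area_numeric <- function(s, window, local_baseline = TRUE) {
  stopifnot(inherits(s, "raman_spectrum"))
  if (length(window) != 2L || window[1L] >= window[2L]) {
    stop("window must be c(lo, hi) with lo < hi", call. = FALSE)
  }
  sel <- s$wavenumber >= window[1L] & s$wavenumber <= window[2L]
  if (sum(sel) < 2L) stop("empty integration window", call. = FALSE)
  x <- s$wavenumber[sel]
  y <- s$intensity[sel]
  if (local_baseline) {
    y <- y - (y[1L] + (y[length(y)] - y[1L]) * (x - x[1L]) / (x[length(x)] - x[1L]))
  }
  pracma::trapz(x, y)
}
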