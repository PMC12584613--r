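## Internal-standard quantification. The Raman band area A of an analyte
## obeys A_a / A_b = (C_a / C_b) (F_a / F_b) for an internal standard "b" of
## constant amount, so the area ratio is linear in analyte concentration.
## With headspace N2 held at fixed pressure the individual cross-sections
## and instrument factors are never needed: they are absorbed into the
## calibration slope.

#' Default sulfate fitting window (cm^-1)
#' @export
SULFATE_WINDOW <- c(930, 1030)

#' Default nitrogen internal-standard fitting window (cm^-1)
#' @export
N2_WINDOW <- c(2280, 2380)

#' Compute the analyte / internal-standard peak-area ratio
#'
#' Both areas come from Gaussian fits ([fit_peaks()]); numeric integration
#' is kept only as a cross-check oracle. When `n_components > 1` the analyte
#' window is deconvolved and the component whose center is nearest
#' `analyte_center` is taken as the analyte (the component nearest the
#' carotenoid companion is thereby excluded deterministically).
#'
#' @param s A (preprocessed) [raman_spectrum()].
#' @param analyte_window Fit window for the analyte band (default sulfate,
#'   930-1030 cm^-1).
#' @param is_window Fit window for the internal standard (default N2,
#'   2280-2380 cm^-1).
#' @param analyte_center Expected analyte band center used to label the
#'   deconvolved components (default 980 cm^-1).
#' @param n_components Components to fit in the analyte window (use 2 when
#'   carotenoids are present).
#' @param init Optional initialization bands for the analyte window.
#' @return The dimensionless area ratio, with attributes `analyte_area`,
#'   `is_area`, `analyte_center_fitted`.
#' @export
compute_ratio <- function(s, analyte_window = SULFATE_WINDOW,
                          is_window = N2_WINDOW, analyte_center = 980,
                          n_components = 1, init = NULL) {
  fit_is <- fit_peaks(s, is_window, n_components = 1)
  a_is <- fit_is$peaks$area[1L]
  rng <- diff(range(s$intensity))
  if (!is.finite(a_is) || a_is <= 1e-9 * rng) {
    stop(paste("internal-standard band area vanishes: no N2 signal in the",
               "standard window (chamber atmosphere assumption violated)"),
         call. = FALSE)
  }
  fit_a <- fit_peaks(s, analyte_window, n_components = n_components, init = init)
  j <- which.min(abs(fit_a$peaks$center - analyte_center))
  a_an <- fit_a$peaks$area[j]
  structure(a_an / a_is,
            analyte_area = a_an, is_area = a_is,
            analyte_center_fitted = fit_a$peaks$center[j])
}

#' Fit an internal-standard calibration model
#'
#' Ordinary least squares of the peak-area ratio on concentration,
#' `ratio = k * C + b`, the form in which calibration lines for
#' internal-standard Raman quantification are reported. Concentration is
#' predicted from a measured ratio by algebraic inversion (see
#' [predict.raman_calibration()]). All replicate points enter the fit
#' individually.
#'
#' @param points A data.frame with columns `conc` (mmol/L) and `ratio`.
#' @param analyte,standard Band descriptors: named lists with `name` and
#'   `window` (stored for provenance; defaults describe sulfate vs N2).
#' @param condition Free-text acquisition condition recorded with the model
#'   (default notes the fixed-pressure N2 headspace).
#' @return An object of class `raman_calibration` with elements `slope`,
#'   `intercept`, `r_squared`, `conc_range`, `n`, `points`, `analyte`,
#'   `standard`, `condition`, and the underlying `lm` fit.
#' @examples
#' pts <- data.frame(conc = c(25, 37.5, 50, 62.5, 75))
#' pts$ratio <- 0.01802 * pts$conc - 0.04239
#' m <- fit_calibration(pts)
#' coef(m)
#' predict(m, ratio = 0.85861)
#' @export
fit_calibration <- function(points,
                            analyte = list(name = "sulfate",
                                           window = SULFATE_WINDOW),
                            standard = list(name = "N2", window = N2_WINDOW),
                            condition = "N2 headspace at 0.3 MPa") {
  if (!all(c("conc", "ratio") %in% names(points))) {
    stop("points must have columns 'conc' and 'ratio'", call. = FALSE)
  }
  concs <- unique(points$conc)
  if (length(concs) < 3L) {
    stop("calibration needs >= 3 distinct concentrations", call. = FALSE)
  }
  if (stats::var(points$conc) == 0) {
    stop("degenerate design: zero concentration variance", call. = FALSE)
  }
  fit <- stats::lm(ratio ~ conc, data = points)
  # suppressWarnings: summary.lm warns on exact (noiseless) series
  structure(list(slope = unname(stats::coef(fit)["conc"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 conc_range = range(points$conc),
                 n = nrow(points),
                 points = points[c("conc", "ratio")],
                 analyte = analyte, standard = standard,
                 condition = condition, lm = fit),
            class = "raman_calibration")
}

#' @export
print.raman_calibration <- function(x, digits = 5, ...) {
  cat("Internal-standard Raman calibration\n")
  cat(sprintf("  %s / %s area ratio = %s * C %s %s\n",
              x$analyte$name, x$standard$name,
              format(x$slope, digits = digits),
              if (x$intercept < 0) "-" else "+",
              format(abs(x$intercept), digits = digits)))
  cat(sprintf("  R^2 = %s on %d points; valid %.4g-%.4g mmol/L (%s)\n",
              format(x$r_squared, digits = digits), x$n,
              x$conc_range[1L], x$conc_range[2L], x$condition))
  invisible(x)
}

#' @export
coef.raman_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
summary.raman_calibration <- function(object, ...) {
  s <- summary(object$lm)
  structure(list(model = object, lm_summary = s), class = "summary.raman_calibration")
}

#' @export
print.summary.raman_calibration <- function(x, ...) {
  print(x$model)
  cat("\nRegression detail:\n")
  stats::printCoefmat(x$lm_summary$coefficients)
  invisible(x)
}

#' Predict concentration from a measured ratio
#'
#' Inverts the calibration line: `C = (ratio - b) / k`. With replicate
#' ratios the concentration is computed per replicate and then averaged
#' (mean +/- SD, matching per-replicate reporting of the quantity of
#' interest). Ratios mapping outside the model's concentration range are
#' flagged `extrapolated`, not rejected: time-course concentrations may
#' drift past the calibrated range.
#'
#' @param object A `raman_calibration`.
#' @param ratio A single measured area ratio (ignored when
#'   `replicate_ratios` is given).
#' @param replicate_ratios Optional vector of replicate area ratios.
#' @param ... Unused.
#' @return A `concentration_estimate`: `value` (mmol/L), `sd` (mmol/L, NA
#'   for a single ratio), `n`, `extrapolated`, `ratio`.
#' @export
predict.raman_calibration <- function(object, ratio = NULL,
                                      replicate_ratios = NULL, ...) {
  if (is.null(replicate_ratios)) {
    if (is.null(ratio)) stop("supply ratio or replicate_ratios", call. = FALSE)
    replicate_ratios <- ratio
  }
  values <- (replicate_ratios - object$intercept) / object$slope
  value <- mean(values)
  sdv <- if (length(values) > 1L) stats::sd(values) else NA_real_
  extrapolated <- value < object$conc_range[1L] | value > object$conc_range[2L]
  if (extrapolated) {
    warning(sprintf(
      "predicted concentration %.3g mmol/L outside calibrated range %.4g-%.4g",
      value, object$conc_range[1L], object$conc_range[2L]), call. = FALSE)
  }
  structure(list(value = value, sd = sdv, n = length(values),
                 extrapolated = extrapolated, ratio = mean(replicate_ratios)),
            class = "concentration_estimate")
}

#' @rdname predict.raman_calibration
#' @param model A `raman_calibration` (functional-interface alias).
#' @export
predict_concentration <- function(ratio, model, replicate_ratios = NULL) {
  if (!is.null(replicate_ratios)) {
    suppressWarnings(predict.raman_calibration(model,
                                               replicate_ratios = replicate_ratios))
  } else {
    suppressWarnings(predict.raman_calibration(model, ratio = ratio))
  }
}

#' @export
print.concentration_estimate <- function(x, ...) {
  sd_txt <- if (is.na(x$sd)) "" else sprintf(" +/- %.3g", x$sd)
  cat(sprintf("%.4g%s mmol/L (n = %d%s)\n", x$value, sd_txt, x$n,
              if (x$extrapolated) ", extrapolated" else ""))
  invisible(x)
}

#' @export
plot.raman_calibration <- function(x, ...) {
  graphics::plot(x$points$conc, x$points$ratio,
                 xlab = "Sulfate concentration (mmol/L)",
                 ylab = sprintf("%s / %s area ratio", x$analyte$name,
                                x$standard$name), pch = 16, ...)
  graphics::abline(x$intercept, x$slope, col = "red3")
  graphics::legend("topleft", bty = "n", legend = sprintf(
    "ratio = %.5f C %s %.5f,  R2 = %.5f", x$slope,
    if (x$intercept < 0) "-" else "+", abs(x$intercept), x$r_squared))
  invisible(x)
}

#' Calibrate directly from a simulated or measured spectrum series
#'
#' Convenience pipeline: despike -> baseline correction -> ratio
#' ([compute_ratio()]) for every spectrum, then [fit_calibration()].
#'
#' @param series List of `list(conc, spectrum)` entries (as produced by
#'   [simulate_calibration_series()]).
#' @param preprocess Run despiking and baseline correction first
#'   (default TRUE).
#' @param baseline_method Passed to [correct_baseline()].
#' @param ... Passed to [compute_ratio()].
#' @return A `raman_calibration`.
#' @export
calibrate_series <- function(series, preprocess = TRUE,
                             baseline_method = "als", ...) {
  pts <- do.call(rbind, lapply(series, function(e) {
    s <- e$spectrum
    if (preprocess) {
      s <- remove_cosmic_rays(s)$spectrum
      s <- correct_baseline(s, method = baseline_method)$corrected
    }
    data.frame(conc = e$conc, ratio = as.numeric(compute_ratio(s, ...)))
  }))
  fit_calibration(pts)
}

#' Serialize a calibration model to JSON
#'
#' Versioned schema containing slope, intercept, R^2, range, band specs,
#' condition and the calibration points; [read_calibration()] restores an
#' equivalent model.
#'
#' @param model A `raman_calibration`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "raman_calibration"))
  obj <- list(schema = "ramanIS/calibration", version = 1L,
              slope = model$slope, intercept = model$intercept,
              r_squared = model$r_squared, conc_range = model$conc_range,
              n = model$n, analyte = model$analyte, standard = model$standard,
              condition = model$condition,
              # documentation alias: the slope equals the analyte/standard
              # quantification-factor ratio divided by the (constant)
              # internal-standard amount
              f_ratio_times_invCb = model$slope,
              points = model$points)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a calibration model from JSON
#' @param path Path to a JSON file written by [write_calibration()].
#' @return A `raman_calibration`.
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "ramanIS/calibration")) {
    stop("not a ramanIS calibration JSON", call. = FALSE)
  }
  pts <- as.data.frame(obj$points)
  m <- fit_calibration(pts, analyte = as.list(obj$analyte),
                       standard = as.list(obj$standard),
                       condition = obj$condition)
  # keep the serialized coefficients authoritative over refitting noise
  m$slope <- obj$slope; m$intercept <- obj$intercept
  m$r_squared <- obj$r_squared
  m$conc_range <- as.numeric(obj$conc_range)
  m
}
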