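---
title: "Internal-standard Raman quantification: model, generator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Internal-standard Raman quantification: model, generator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanIS)
```

## The quantification model

Raman band intensity is proportional to analyte amount, but the
proportionality constant bundles the scattering cross-section of the
vibrational mode with excitation power and instrument response. None of
those are knowable to useful accuracy, so absolute intensities cannot be
compared across acquisitions. Ratioing against an internal standard of
constant amount removes all of them at once: for analyte *a* and standard
*b*,

$$\frac{A_a}{A_b} \;=\; \frac{C_a}{C_b}\cdot\frac{\sigma_a}{\sigma_b}
\cdot\frac{\eta_a}{\eta_b} \;=\; \frac{C_a}{C_b}\cdot\frac{F_a}{F_b},$$

with $A$ the fitted band area, $C$ the concentration, $\sigma$ the
cross-section, $\eta$ the instrument factor, and $F = \sigma\eta$ the
quantification factor. Here the standard is headspace N~2~ over the
gas–solid interface of a solid medium, held at 0.3 MPa so $C_b$ is
constant. The individual $\sigma$ and $\eta$ values are never estimated —
they are not identifiable from ratio data and are not needed: everything
collapses into the slope of the calibration line

$$A_{\mathrm{SO_4}}/A_{\mathrm{N_2}} \;=\; k\,C_{\mathrm{SO_4}} + b,$$

fitted by ordinary least squares of ratio on concentration
(`fit_calibration()`), with concentration recovered by algebraic inversion
(`predict()`). The regression runs in this direction (ratio on
concentration) because that is the form in which such calibrations are
reported; inverting the fitted line is exact algebra and introduces no
additional assumption. All replicate points enter the regression
individually rather than as per-concentration means — with balanced
replication the line is identical and the residual spread stays visible in
$R^2$.

Predictions outside the calibrated range (25–75 mmol/L with the default
generator) are flagged `extrapolated`, not refused: during a time course
the true concentration may drift past the calibrated interval, and a
flagged estimate is more useful than an error. Replicate spectra are
converted to concentrations *per replicate* and then averaged, so the
reported mean ± SD is the statistic of the quantity of interest, not of the
intermediate ratio.

## What the generator emulates

No raw spectra are deposited for this measurement system, so the package
ships a scene generator with exact bookkeeping, and all validation runs
against generator truth.

A scene is a sum of Gaussian bands
$h\exp\!\left(-4\ln 2\,(\nu - c)^2/w^2\right)$ (so the analytic area is
$h\,w\sqrt{\pi/(4\ln 2)}$), a polynomial baseline, i.i.d. Gaussian noise,
and optional single-channel cosmic-ray spikes. The default band table
mirrors the interface spectrum of a sulfur-disproportionating colony:

| band | center (cm⁻¹) | FWHM (cm⁻¹) | amplitude |
|---|---|---|---|
| N₂ (internal standard) | 2332 | 10 | fixed, 1000 counts |
| sulfate S–O stretch | 980 | 8 | set by concentration |
| S₈ S–S | 470 | 10 | `s8_level` |
| carotenoid companions | 1005, 1157 | 12, 12 | 0.35 / 0.80 × level |
| carotenoid polyene C=C | 1523 | 14 | `carotenoid_level` |

Design notes, each fixed once:

* **Gaussian line shape, not Voigt.** The analysis fits Gaussians, so the
  generator uses the same family; parameter recovery is then exact in the
  noiseless limit and any residual error is attributable to the pipeline,
  not to model mismatch.
* **The sulfate amplitude encodes the calibration line.** At concentration
  $C$ the sulfate band height is chosen so the sulfate/N₂ *area* ratio is
  exactly $0.01802\,C - 0.04239$. A generated calibration series therefore
  has a known true slope and intercept, and end-to-end recovery is a
  meaningful test of the whole chain.
* **The N₂ height is constant** because the headspace pressure is constant
  — that is the entire premise of the internal standard.
* **Carotenoid companions at 1005 and 1157 cm⁻¹.** Only the 1523 cm⁻¹
  band is needed for imaging, but real carotenoid spectra have companion
  bands, one of which falls inside the sulfate fitting window; the 1005
  band exists precisely so the overlapping-band deconvolution path is
  exercised. The companion centers and relative heights are generator
  conventions.
* **Axis 200–2500 cm⁻¹ at 1 cm⁻¹ spacing**: the instrument's resolution is
  3 cm⁻¹, so 1 cm⁻¹ sampling is ~3× oversampled, which keeps Gaussian fits
  well conditioned without inflating cost.
* **Noise is additive i.i.d. Gaussian on counts.** The default calibration
  noise SD (4 counts) was calibrated once by Monte Carlo so the fitted
  sulfate-area relative error is ≈ 0.5% at mid-range concentration; the
  low-noise variant (0.8 counts) gives ≈ 0.1%. No shot-noise or
  fluorescence physics is modeled (see limitations).

### Kinetics

Sulfate production by thiosulfate disproportionation shows three phases —
slow early rise, fast mid-incubation production, late plateau — which a
logistic captures with four parameters. Darkness slows the metabolism and
prolongs the whole synthesis cycle, so the dark condition is modeled as a
*dilation of the metabolic time axis*:

$$c(t) \;=\; c_0 + \frac{c_{\max}-c_0}
{1+\exp\!\big(-r\,(\ell t - t_{\mathrm{mid}})\big)},$$

with $\ell = 1$ under light and $\ell < 1$ in the dark. The effective rate
is $r\ell$ and the inflection is delayed to $t_{\mathrm{mid}}/\ell$ — a
dark course is exactly the light course stretched in time by $1/\ell$. An
alternative parameterization that scales the rate around a *shared*
inflection was rejected: it makes both conditions cross their
concentration midpoint at the same time, so the observable "the cycle is
prolonged in the dark" would vanish from the simulation. Defaults:
$c_0 = 30$, $c_{\max} = 70$ mmol/L, $t_{\mathrm{mid}} = 40$ h,
$r = 0.15$ h⁻¹, dark $\ell = 0.4$.

## Preprocessing choices

**Pipeline order is fixed**: despike → baseline → (optional) wavenumber
correction → average. Spikes are narrow and huge, so they corrupt any
baseline estimate made before their removal.

**Despiking.** Cosmic rays are one-to-two-channel impulses, far narrower
than the ~3 cm⁻¹ instrument linewidth. A channel is flagged when the robust
z-score of its residual from a running-median smooth (window 5 channels)
exceeds 8. A plain modified z-score of the raw first differences was
rejected: on a low-noise spectrum the MAD of the differences collapses
toward zero and the flanks of genuine bands are flagged as spikes. Two
safeguards make the detector specific: detrending by the running median
(band flanks survive a 5-channel median almost unchanged, impulses do not),
and flooring the robust scale at 1% of the spectrum's intensity range so
that a noiseless spectrum cannot produce false positives. Flagged channels
are replaced by the median of the surrounding window, excluding other
flagged channels, so adjacent double spikes repair correctly. The window
should stay below the narrowest genuine band's FWHM in channels; bands
narrower than ~5 channels would risk being clipped.

**Baseline.** Two estimators: Eilers-style asymmetric least squares
(sparse banded solve, 10 reweighting iterations) and an iterative
restricted polynomial fit (degree ≤ 6). ALS defaults are
$\lambda = 10^6$, $p = 0.001$: with a softer $p$ of 0.01 the baseline
creeps ~0.4% of band height up under isolated peaks, while 0.001 keeps the
under-peak bias below 0.1% of height and recovers a quadratic baseline
under a 1000-count band to within 0.25 counts. The corrected spectrum is
defined as input minus baseline, so the additive decomposition is exact by
construction.

**Wavenumber calibration.** The silicon reference band is fitted with a
single Gaussian in 470–570 cm⁻¹; the fitted center minus 520 cm⁻¹ is
subtracted from the axis. Offsets ≥ 50 cm⁻¹ are rejected as implausible
(that is a gross misalignment, not a calibration drift). The correction is
idempotent: re-estimating on a corrected spectrum returns ~0.

## Peak fitting

`fit_peaks()` does bounded nonlinear least squares (Levenberg–Marquardt via
minpack.lm) on a sum of 1–5 Gaussians inside a window:

* A **local linear chord** through the window endpoints is removed before
  fitting, even after global baseline correction — the global estimate
  cannot be assumed perfect, and the chord makes the fit invariant to any
  residual constant or linear offset.
* **Bounds**: centers inside the window, FWHM between 2× the channel
  spacing and the window width, heights ≥ 0. Bounds prevent component
  swapping during deconvolution.
* **Initialization** from the n largest local maxima (or explicit `init`
  bands); up to 5 restarts with seeded jittered starts guard against local
  minima in multi-component fits. A request for more components than there
  are local maxima without explicit initialization is an error, not a
  guess.
* **Labeling after deconvolution** is deterministic: the component nearest
  980 cm⁻¹ is the sulfate band; the component nearest the carotenoid
  companion is thereby excluded.
* Standard errors come from the analytic Jacobian of the Gaussian sum;
  the area SE uses the delta method on $h\,w\sqrt{\pi/(4\ln 2)}$.

Default windows — sulfate 930–1030 cm⁻¹ (2 components when carotenoids are
present), N₂ 2280–2380 cm⁻¹ — are package choices; trapezoidal integration
(`peak_area_numeric()`) is retained as a model-free cross-check of the
analytic areas, not as the production path.

## Imaging and time courses

Band images integrate each map node over center ± 10 cm⁻¹ (the
conventional windows for S₈ at 470 and carotenoids at 1523 cm⁻¹), after
subtracting the endpoint chord per node; whether vendor software does the
same is undocumented, so the chord is switchable. Negative node integrals
are clipped to zero and counted. Map grids are stored row-major by
ascending y then x so output is bit-reproducible.

Time-course rates deliberately avoid fitting a named growth model: the
maximum production rate is the largest sliding-window (3-point)
least-squares slope, with ties broken to the earliest window. The
"synthesis-cycle length" surrogate is the time of first crossing of the
midpoint between initial and final mean concentration, linearly
interpolated. Both statistics are invariant to adding a constant to all
concentrations.

## Problem sizes and what the tests show

The test suite and the acceptance script use desk-scale problems chosen as
representative: calibration at 5 concentrations × 3 replicates on the
default 2301-channel axis; colony maps up to 11 × 11 nodes; time courses of
9 points × 2–3 replicates; 100 paired light/dark simulations for the
ordering property. Passing them demonstrates that the pipeline recovers
known synthetic truth under the stated noise model — it does *not*
demonstrate robustness to the things the generator omits: photon shot
noise, fluorescence backgrounds with structure, instrument line-shape
convolution, detector nonlinearity, focus drift, or the undisclosed details
of vendor preprocessing. Equivalence with vendor software cannot be
asserted, only recovery of synthetic truth.

## Known limitations

* Gaussian-only line shapes; no Voigt/Lorentzian option.
* No automatic selection of the number of fit components.
* Unweighted OLS calibration; no Deming or weighted regression.
* Depth-resolved (x, y, z) mapping and depth-dependent signal correction
  are out of scope.
* The N₂ internal standard presumes a fixed-pressure nitrogen headspace;
  the package checks only that the N₂ band is present, not that the
  pressure was actually constant.
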