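# ramanIS

Internal-standard Raman quantification of sulfate in solid culture media,
with the full supporting spectral-processing chain.

## The problem

Confocal Raman microspectroscopy can watch microbial sulfur metabolism *in
situ*: sulfate, cyclooctasulfur (S₈) and carotenoids each have
characteristic vibrational bands, so colonies growing on an agar surface can
be monitored for days without sampling. But raw Raman intensity is useless
for absolute quantification — it depends on laser power, focus, collection
optics and the scattering cross-section of each analyte. For metabolites
that are *already present* in the medium (sulfate is a major seawater
constituent), presence/absence imaging cannot quantify anything.

The remedy is an internal standard of constant amount. When spectra are
acquired at the gas–solid interface under a nitrogen headspace held at fixed
pressure, the N₂ stretching band at 2,332 cm⁻¹ is always in view and its
amount never changes. For two species a (analyte) and b (standard), the
ratio of characteristic peak areas obeys

```
A_a / A_b = (C_a / C_b) · (σ_a / σ_b) · (η_a / η_b) = (C_a / C_b) · (F_a / F_b)
```

where σ is the Raman scattering cross-section and η the instrument response;
F = σ·η is the quantification factor. Every instrument-dependent term
cancels or is constant, so the area ratio is linear in analyte
concentration:

```
A_SO4 / A_N2 = k · C_SO4 + b
```

`ramanIS` implements this calibration model and everything around it:

* **synthetic scenes** — Gaussian bands + polynomial baseline + noise +
  cosmic-ray spikes with exact ground truth (no raw spectra are publicly
  deposited for this kind of measurement, so validation runs on simulated
  data);
* **preprocessing** — cosmic-ray despiking, asymmetric-least-squares or
  polynomial baseline correction, wavenumber calibration against the
  520 cm⁻¹ silicon reference, replicate averaging;
* **peak fitting** — bounded multi-Gaussian least squares, including
  deconvolution of the carotenoid band that overlaps the sulfate S–O
  stretch at 980 cm⁻¹;
* **quantification** — area-ratio computation, ordinary-least-squares
  calibration (`raman_calibration` objects with `print`/`coef`/`predict`/
  `plot` methods), inverse concentration prediction with range checking;
* **imaging** — univariate band-integration maps (S₈ at 470 ± 10 cm⁻¹,
  carotenoids at 1,523 ± 10 cm⁻¹) from gridded spectral maps;
* **time courses** — concentration-vs-time curves with replicate SDs,
  model-free maximum production rates, and light-vs-dark comparisons.

## Worked example

Simulate a calibration series (5 concentrations × 3 replicates, ~0.5%
area noise), run the full pipeline, and quantify a fresh spectrum of
unknown concentration:

```r
library(ramanIS)

series <- simulate_calibration_series(seed = 42)   # 15 synthetic spectra
model  <- calibrate_series(series)                 # despike -> baseline -> fit -> OLS
model
#> Internal-standard Raman calibration
#>   sulfate / N2 area ratio = 0.018048 * C - 0.041568
#>   R^2 = 0.99935 on 15 points; valid 25-75 mmol/L (N2 headspace at 0.3 MPa)

# a fresh noisy spectrum at 60 mmol/L (truth known to the generator only)
s <- simulate_spectrum(scene_truth(default_interface_bands(60), noise_sd = 4, seed = 99))
s <- correct_baseline(remove_cosmic_rays(s)$spectrum)$corrected
predict(model, ratio = as.numeric(compute_ratio(s)))
#> 59.92 mmol/L (n = 1)

fit_peaks(s, c(930, 1030), 1)
#> Gaussian peak fit: 1 component(s) in 930.0-1030.0 cm^-1
#>   center  fwhm height  area
#> 1    980 8.014   1301 11098
#> residual SD: 3.868 CCD counts
```

The recovered slope (0.01805) and intercept (−0.0416) sit within a percent
or two of the generator's true line (0.01802·C − 0.04239), and the fresh
60 mmol/L spectrum is predicted at 59.9 mmol/L.

A command-line interface wraps the same functions
(`inst/exec/ramanIS`): `simulate`, `preprocess`, `fit`, `calibrate`,
`quantify`, `map` and `timecourse` subcommands, all seeded and
config-driven.

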