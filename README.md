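# foragenirs

Chemometric calibration of forage nutritive value from near-infrared
reflectance spectra, for forage and feed scientists who need a tested,
reusable implementation of the standard NIRS modelling workflow — and a
physically motivated simulator for benchmarking it when no spectra can
be shared.

## What it does

Forage quality is summarized by six laboratory constituents, all in % of
dry matter: neutral detergent fiber (NDF), in vitro true digestibility
(IVTD), NDF digestibility (NDFD), acid detergent fiber (ADF), acid
detergent lignin (ADL) and crude protein (CP). NIRS calibration regresses
these reference values on reflectance spectra. `foragenirs` implements:

- **NIPALS PLS1** (`pls_nipals()`), written from scratch with
  per-component explained-X-variance accounting. Latent variables are
  selected as the smallest count explaining 95 % of the X variance,
  capped at one component per 10 calibration samples (`select_lvs()`).
- **The spectral preprocessing grid** (`enumerate_grid()`): absorbance
  conversion log10(1/R), wavelength trimming, standard normal variate +
  detrend, and Savitzky–Golay smoothing/derivatives over odd windows
  9–27, polynomial order 2–3 and derivative order 0–2 — 122 recipes.
- **Venetian-blinds cross-validation** (5 splits, thickness 1) and an
  odd-harvest-date validation split (`split_by_harvest()`), orchestrated
  by `forage_calibration()`, which searches the grid by SECV, refits the
  winner and scores the held-out partition.
- **The NIRS error statistics**: SEC and SECV with the N−1−LV
  denominator, RMSEP (N−1), bias-corrected SEP, bias, slope, R², and the
  laboratory-error ceiling R²MAX = (SDL² − SEL²)/SDL² (`r2max()`).
- **A two-instrument simulator** (`make_dataset()`): Beer–Lambert
  mixture spectra from Gaussian absorption-band libraries, rendered on a
  2 nm benchtop scanning monochromator and a 16 nm handheld
  Fourier-transform instrument with a variable 2.5–8.8 nm step, plus
  laboratory-noised reference values — so the whole pipeline, including
  the instrument comparison (`compare_models()`,
  `per_wavelength_r2()`), runs end to end without proprietary data.

The methods vignette (`vignettes/forage-nirs-calibration.Rmd`) documents
the model, every convention the package had to fix, and what the
simulator does and does not emulate.

## Worked example

```r
library(foragenirs)
dataset <- make_dataset(sim_scenario(n_samples = 160, seed = 7))
grid <- enumerate_grid()[c(1, 33, 62, 94)]   # a 4-recipe mini grid
fit <- forage_calibration(dataset$foss, dataset$observed, dataset$meta,
                          constituents = c("NDF", "ADF", "CP"), grid = grid)
fit
```

```
Forage NIR calibration (benchtop_2nm): 118 calibration / 42 validation samples

Calibration (SEC, SECV from venetian-blinds CV):
 constituent                                                preprocess lv   sec
         NDF             log1R+trim(1350,2498)+sg(w=19,p=2,d=1)+center  4 0.619
         ADF log1R+trim(1350,2498)+snv_detrend+sg(w=19,p=2,d=1)+center  4 0.913
          CP             log1R+trim(1350,2498)+sg(w=19,p=2,d=1)+center  4 0.289
   r2c  secv  r2cv
 0.984 0.653 0.983
 0.975 1.038 0.967
 0.997 0.306 0.997

Validation (held-out odd harvest dates):
 constituent  n   r2p rmsep   sep     bias slope
         NDF 42 0.983 0.592 0.591 -0.02617 0.977
         ADF 42 0.971 1.018 0.996  0.20538 0.986
          CP 42 0.997 0.246 0.246  0.00617 1.006
```

Reading the output: each constituent's winning preprocessing recipe (here
a first-derivative Savitzky–Golay filter), the latent-variable count the
95 %-variance rule selected (4), the calibration-side errors (SEC, and
SECV from venetian-blinds cross-validation, % DM), and the held-out
validation errors. SEP is RMSEP with the mean bias removed; with the
simulator's laboratory noise at SEL = 0.45 (NDF), 0.74 (ADF) and 0.21
(CP) % DM, validation SEPs of 0.59, 1.00 and 0.25 sit close to the
information floor set by the reference assays. The attainable-R² ceilings
from the packaged constituent statistics:

```r
st <- forage_constituent_stats()
setNames(round(mapply(r2max, st$sd, st$sel), 2), st$constituent)
#>  NDF IVTD NDFD  ADF  ADL   CP
#> 0.99 1.00 0.99 0.98 0.94 1.00
```

For the full two-instrument study — both instruments calibrated on the
same samples, compared constituent by constituent — run
`calibrate_and_validate(make_dataset(sim_scenario()))` (a few minutes),
and `write_reports()` to export the report CSVs and a run manifest.

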