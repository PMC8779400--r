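---
title: "Calibrating forage nutritive value from NIR spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating forage nutritive value from NIR spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Near-infrared reflectance spectroscopy (NIRS) predicts forage nutritive
value — neutral detergent fiber (NDF), in vitro true digestibility (IVTD),
NDF digestibility (NDFD), acid detergent fiber (ADF), acid detergent
lignin (ADL) and crude protein (CP), all in % of dry matter — from the
reflectance spectrum of a dried, ground sample, replacing slow and costly
wet-chemistry assays. A calibration is a regression of laboratory
reference values on spectra; its practical worth is judged by prediction
error on samples the model has never seen, and its ceiling is set by the
replicate error of the laboratory reference itself.

`foragenirs` implements the complete calibration workflow in the classic
R modelling idiom — a fitting function returning a classed object with
`print`, `summary`, `coef`, `predict`, `plot` and `residuals` methods —
together with a physically motivated simulator of paired two-instrument
data, so that every stage is testable without proprietary spectra.

# The model

## NIPALS PLS1

Spectra have hundreds of collinear channels; partial least squares
regression (PLS) is the field's standard answer. For a univariate
response, the NIPALS algorithm extracts latent variables (LVs)
sequentially from the centered matrices. At each round the weight vector
is the fixed point of the NIPALS inner iteration, available in closed
form as the normalized covariance direction

$$ w_a = X_a^\top y_a / \lVert X_a^\top y_a \rVert, \qquad
   t_a = X_a w_a, \quad p_a = X_a^\top t_a / t_a^\top t_a, \quad
   q_a = y_a^\top t_a / t_a^\top t_a, $$

followed by deflation $X_{a+1} = X_a - t_a p_a^\top$,
$y_{a+1} = y_a - q_a t_a$. Because the univariate fixed point is exact,
the fit is deterministic and tolerance-free; the `tol` and `max_iter`
arguments of `pls_nipals()` exist for interface completeness only.
Component $a$ explains $100\,\lVert t_a p_a^\top\rVert_F^2 /
\lVert X_1 \rVert_F^2$ percent of the centered predictor sum of squares,
and prediction collapses to the affine map
$\hat y = \bar y + (x - \bar x)^\top W (P^\top W)^{-1} q$.

The number of latent variables is chosen by `select_lvs()`: the smallest
count whose cumulative explained X variance reaches a threshold (95 % by
default; 99 % is exposed as the aggressive variant), capped so that at
least 10 calibration samples support each component. We read "10 data
points per LV" as $N/\mathrm{LV} \ge 10$ on the calibration set; a
per-fold reading is also defensible but cannot be distinguished without
the original data. An optional `overfit_guard()` (off by default)
compares the cross-validation error over 1..k components and backs off
only when a smaller model wins by more than 1 % relative.

## Preprocessing

All recipes share a fixed transform order: reflectance to absorbance
($A = \log_{10} 1/R$), wavelength trim (default 1350–2498 nm, the
overlap of the two emulated instruments), optional standard normal
variate + polynomial detrend, optional Savitzky–Golay filter, and
mean-centering. Choices worth stating:

* **Detrend degree is 2**, the convention of the SNV-detrend literature;
  it is exposed as a parameter since only "detrend" is conventionally
  specified.
* **SNV precedes differentiation.** The order is not configurable:
  scatter correction before derivatives is the common chemometric order,
  and freezing it keeps the sensitivity grid well-defined.
* **Savitzky–Golay derivatives are per channel index**, and the
  `(window-1)/2` edge channels are dropped rather than padded — padding
  invents data. On a uniform grid the index/nm distinction is a constant
  factor absorbed by the regression coefficients. Spectra on a
  non-uniform grid (the handheld's) are first resampled to a uniform
  2 nm grid over the trimmed range; the filter is undefined on irregular
  grids and this resolution is stated here because no convention exists.
* **Centering statistics always come from the calibration partition**
  (and, inside cross-validation, from the in-fold training samples
  only), preventing information leakage. Per-spectrum transforms (SNV,
  detrend, Savitzky–Golay) use no cross-sample statistics, so they may
  be computed once for a dataset without leaking.

The sensitivity grid `enumerate_grid()` crosses scatter correction
(off / SNV+detrend) with either no Savitzky–Golay step or every odd
window 9–27, polynomial order 2–3 and derivative order 0–2 (derivative
never exceeding the polynomial order): 2 × (1 + 10 × 6) = 122 recipes in
a fixed order. Whether scatter correction and derivatives were meant as
alternatives or combinable is ambiguous in common practice; the grid
includes both combinations.

## Validation design

`split_by_harvest()` segregates samples from odd-numbered harvest dates
as the validation set *before* any model development. Cross-validation
inside the calibration set uses venetian blinds with five splits and a
blind thickness of one: sample $i$ (dataset order, never shuffled — the
order is part of the input contract) goes to fold
$\lfloor (i-1)/\text{thickness}\rfloor \bmod \text{splits}$.
`grid_search()` scores every recipe by SECV on pooled out-of-fold
predictions and picks the minimum; within a 1 % relative band of that
minimum the recipe with the smallest $|SECV - SEC|$ gap wins
(simultaneously minimizing the error and the calibration/CV gap), with
remaining ties broken by grid order. The search runs per constituent; a
`shared_preprocess = TRUE` flag instead picks the single recipe
minimizing mean SECV across constituents.

## Error statistics

With laboratory values $L$ and predictions $P$ over $N$ samples:

$$ SEC(V) = \sqrt{\frac{\sum (L_i - P_i)^2}{N - 1 - LV}}, \qquad
   RMSEP = \sqrt{\frac{\sum (L_i - P_i)^2}{N - 1}}, \qquad
   SEP = \sqrt{\frac{\sum (L_i-P_i)^2 - (\sum (L_i-P_i))^2/N}{N - 1}}. $$

These satisfy exactly $(N-1)\,RMSEP^2 = (N-1)\,SEP^2 + N\,\text{bias}^2$,
which the test suite asserts on random residuals. Conventions that had to
be fixed where none is universal:

* **bias** $= \bar P - \bar L$ (a flag flips the sign convention);
  **slope** is the OLS slope of $L$ regressed on $P$, i.e. the line of a
  laboratory-vs-predicted scatter plot.
* **R²** is the squared Pearson correlation in all three contexts
  (calibration, CV, prediction), so it is affine-invariant and bias and
  slope carry the systematic-error information separately.
* **RMSEP uses the $N-1$ denominator** as printed in the NIRS reporting
  tradition this package follows; a flag offers plain $N$. SECV charges
  degrees of freedom for the latent variables ($N-1-LV$), with a flag to
  use $N-1$.

The ceiling on attainable R² given laboratory error is
$R^2_{MAX} = (SD_L^2 - SEL^2)/SD_L^2$ (`r2max()`), where $SD_L$ is the
calibration-set spread and $SEL$ the standard error of the laboratory.
It is clamped to 0 with a warning when $SEL \ge SD_L$ — a negative
attainable variance is meaningless and signals an uninformative dataset.
Applied to the packaged constituent statistics
(`forage_constituent_stats()`), the ceilings are 0.99 (NDF), 1.0 (IVTD),
0.99 (NDFD), 0.98 (ADF), 0.94 (ADL) and 1.0 (CP) at reporting precision,
which `scripts/acceptance.R` recomputes.

# The simulator

No spectra were deposited with the study this package operationalizes,
so `make_dataset()` generates paired two-instrument data with the
statistical structure of a mixed alfalfa/grass database:

* **Concentrations.** A Gaussian copula draws six correlated constituent
  values per sample: multivariate-normal dependence under an invented
  but sign-correct correlation matrix (fiber fractions nested
  chemically, protein trading off against fiber, digestibility tracking
  fiber negatively; `default_correlations()`, projected to the nearest
  PSD matrix), with each margin mapped through a truncated-normal
  quantile function. Parent parameters are moment-matched in closed form
  so the *truncated* margins reproduce the target means and SDs —
  truncation would otherwise shrink both. Two boxes are tight enough to
  cap the attainable SD near the uniform limit $(\max-\min)/\sqrt{12}$
  (IVTD: 12.4 vs. target 13; ADF: 5.77 vs. 5.8); the sampler converges
  to the attainable optimum, and the tests assert fidelity against it.
  A joint box-rejection sampler was tried first and abandoned: with
  near-uniform parents the joint acceptance region distorts the other
  marginals through the correlations.
* **Spectra.** Beer–Lambert mixing: each constituent carries a sum of
  Gaussian absorption bands (4 by default, centers 1350–2498 nm, widths
  25–70 nm SD), and a sample's true absorbance is the
  concentration-weighted sum plus a smooth shared baseline
  (0.35 + 0.15 λ_norm AU). Band heights are scaled to
  `height_scale / SD_k` (3/SD_k AU per %DM by default) so every
  constituent imprints a comparable share of spectral variance, as the
  major constituents of real forage do; this also makes the latent
  dimension of the spectra the constituent count, so the
  95 %-explained-variance rule lands at 4–6 LVs, the range reported for
  such calibrations.
* **Instruments.** The benchtop monochromator samples 1100–2498 nm at a
  fixed 2 nm step with a 2 nm Gaussian line shape and 5×10⁻⁴ AU
  photometric noise; the handheld Fourier-transform device samples
  1350–2550 nm at a step growing arithmetically from 2.5 to 8.8 nm with
  a 16 nm line shape and 2×10⁻³ AU noise (handheld photometric noise is
  not publicly characterized; this default is a documented, adjustable
  guess). The arithmetic step progression realizes "variable step
  between 2.5 and 8.8 nm" as monotone coarsening toward long
  wavelengths, matching Fourier-transform behavior in wavelength units.
  Rendering convolves the true absorbance with the line shape on a 1 nm
  internal grid, samples onto the instrument grid, adds per-sample
  multiplicative/additive scatter (SD 0.005 and 0.001 AU) and iid noise,
  and returns reflectance $R = 10^{-A}$ clipped to [10⁻⁶, 1.5]. The
  scatter SDs are deliberately small: particle-size scatter is chiefly a
  property of the ground sample, shared between instruments scanning the
  same cup, and only the per-acquisition component belongs in the
  instrument model. With these defaults the per-wavelength
  inter-instrument agreement of absorbance sits near R² ≈ 0.8, the right
  regime for well-prepped dried ground samples.
* **Design.** 384 samples by default, 104 labelled alfalfa; harvest
  dates are assigned so that 100 samples land on odd dates (the held-out
  partition) and 284 on even dates, interleaved evenly through the
  dataset. A uniform cyclic date assignment cannot produce a minority
  validation share, so the interleave is this package's emulation of a
  study whose odd harvest dates held out roughly a quarter of the
  database. Species labels do not alter the generative model — the
  mixed-species calibration is the implemented path, and per-species
  subsetting is left to the user.

What the simulator does **not** emulate: radiative-transfer and
particle-size physics, wavelength-repeatability drift, temperature
effects, species-specific spectral signatures, and non-Gaussian
laboratory error. Passing the end-to-end tests therefore demonstrates
that the pipeline recovers constituents down to the laboratory noise
floor on data satisfying the Beer–Lambert assumptions — not that any
particular real instrument will achieve those errors.

```{r}
library(foragenirs)
dataset <- make_dataset(sim_scenario())
study <- calibrate_and_validate(dataset)
study
```

# Numerical choices and degenerate inputs

* NIPALS stops early if the response variance is exhausted
  (‖Xᵀy‖ < 10⁻¹⁴) and refuses zero-variance responses outright.
* `sep()` clips radicands in (−10⁻¹², 0) to zero and errors on anything
  more negative.
* `r2max()` clamps to 0 (with a warning and a `clamped` attribute) when
  SEL ≥ SDL.
* Grid-search failures of individual recipes (e.g. too few channels
  after a wide filter) are recorded as `NA` rows, not fatal errors; only
  an all-recipe failure aborts.
* Ties: grid order is the deterministic tie-break everywhere; venetian
  folds never shuffle.
* Reflectance is a fraction in (0, 1.5] — values above 1 tolerate
  white-reference drift; percent-scale input is rejected since
  $\log_{10} 1/R$ requires the fractional convention. Whether a given
  instrument stores reflectance or absorbance natively varies, so
  `read_spectra()` takes an explicit `signal_kind`.
* No outlier-removal stage is implemented: none is defined in the
  reporting tradition this package follows, and silently deleting
  samples would undermine the validation contract.

# Problem sizes in the test suite

The packaged tests run the complete two-instrument study once at the
default scenario (384 samples, full 122-recipe grid, six constituents —
a few minutes of CPU) and reuse it across assertions; marginal-fidelity
checks draw 5000 samples; oracle comparisons (ordinary least squares at
full rank, an independent PLS implementation at 1–5 components) run on
100 seeded problems of at most 50 × 30. These sizes were chosen to make
stochastic tolerances tight while keeping a full check quick on a
laptop.

# Known limitations

* PLS1 only — one model per constituent, as is standard for forage
  calibration reporting. No PLS2, kernel, sparse or orthogonal variants.
* No calibration transfer between instruments (direct standardization
  and friends are out of scope); the instrument comparison is by
  parallel calibration, not spectral mapping.
* Confidence intervals on SEP and significance tests between instruments
  are not provided.
* The venetian-blinds contract makes fold assignment depend on dataset
  order; users supplying their own data should be deliberate about row
  order (e.g. chronological), as the original method intends.
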