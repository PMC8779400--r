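# Synthetic two-instrument forage NIR data.
#
# A Beer-Lambert mixture model: each constituent carries an absorptivity
# curve built from Gaussian absorption bands; a sample's true absorbance is
# the concentration-weighted sum of those curves plus a smooth baseline.
# Instruments differ in wavelength grid, line-shape width and photometric
# noise; samples additionally receive multiplicative/additive scatter.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Reference distribution of forage constituents
#'
#' The packaged summary statistics of a mixed alfalfa/grass calibration
#' set (284 samples): per-constituent minimum, mean, maximum and standard
#' deviation in % DM, plus the standard error of the laboratory (SEL) of
#' each reference assay. These are the default marginals of
#' [sim_scenario()] and the SDL/SEL inputs of [r2max()].
#'
#' @return A data frame with columns `constituent`, `min`, `mean`, `max`,
#'   `sd`, `sel`, rows NDF, IVTD, NDFD, ADF, ADL, CP.
#' @export
forage_constituent_stats <- function() {
  path <- system.file("extdata", "forage_constituent_stats.csv",
                      package = "foragenirs", mustWork = TRUE)
  utils::read.csv(path)
}

#' Default between-constituent correlation matrix
#'
#' Fiber fractions are chemically nested (NDF contains ADF contains ADL),
#' protein trades off against fiber, and digestibility tracks fiber
#' negatively -- the matrix encodes those signs with plausible magnitudes
#' and is projected to the nearest positive semi-definite correlation
#' matrix. It is a scenario knob, not an estimate.
#'
#' @return A 6 x 6 PSD correlation matrix over NDF, IVTD, NDFD, ADF,
#'   ADL, CP.
#' @export
default_correlations <- function() {
  nm <- c("NDF", "IVTD", "NDFD", "ADF", "ADL", "CP")
  R <- diag(6)
  dimnames(R) <- list(nm, nm)
  pairs <- rbind(c("NDF", "ADF", 0.85), c("NDF", "ADL", 0.6),
                 c("ADF", "ADL", 0.7), c("NDF", "CP", -0.6),
                 c("IVTD", "NDF", -0.5), c("NDFD", "IVTD", 0.8))
  for (i in seq_len(nrow(pairs))) {
    v <- as.numeric(pairs[i, 3])
    R[pairs[i, 1], pairs[i, 2]] <- v
    R[pairs[i, 2], pairs[i, 1]] <- v
  }
  as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
}

#' Describe an instrument for spectral simulation
#'
#' @param label instrument label carried onto generated spectra.
#' @param grid_start_nm,grid_end_nm wavelength range bounds (nm).
#' @param step_nm fixed sampling step (nm); exclusive with
#'   `step_range_nm`.
#' @param step_range_nm length-2 vector `c(step_min, step_max)`: the grid
#'   steps grow as an arithmetic progression from `step_min` at the short-
#'   wavelength end to `step_max` at the long end (monotone coarsening in
#'   wavelength units, as in Fourier-transform instruments).
#' @param lineshape_fwhm_nm full width at half maximum of the Gaussian
#'   line shape the true spectrum is convolved with.
#' @param noise_sd_absorbance iid photometric noise SD, absorbance units.
#' @param scatter_mult_sd,scatter_add_sd per-sample multiplicative and
#'   additive-offset scatter SDs applied to the true absorbance.
#' @return An object of class `instrument_model` with the realized `grid`.
#' @export
instrument_model <- function(label, grid_start_nm, grid_end_nm,
                             step_nm = NULL, step_range_nm = NULL,
                             lineshape_fwhm_nm, noise_sd_absorbance,
                             scatter_mult_sd = 0.005, scatter_add_sd = 0.001) {
  stopifnot(grid_start_nm < grid_end_nm, lineshape_fwhm_nm > 0,
            xor(is.null(step_nm), is.null(step_range_nm)))
  if (!is.null(step_nm)) {
    grid <- seq(grid_start_nm, grid_end_nm, by = step_nm)
  } else {
    smin <- step_range_nm[1]; smax <- step_range_nm[2]
    n_steps <- round((grid_end_nm - grid_start_nm) / mean(step_range_nm))
    steps <- seq(smin, smax, length.out = n_steps)
    grid <- grid_start_nm + c(0, cumsum(steps))
    grid <- grid[grid <= grid_end_nm + 1e-9]
  }
  structure(list(label = label, grid_start_nm = grid_start_nm,
                 grid_end_nm = grid_end_nm, grid = grid,
                 lineshape_fwhm_nm = lineshape_fwhm_nm,
                 noise_sd_absorbance = noise_sd_absorbance,
                 scatter_mult_sd = scatter_mult_sd,
                 scatter_add_sd = scatter_add_sd),
            class = "instrument_model")
}

#' @exportS3Method base::print
print.instrument_model <- function(x, ...) {
  cat("<instrument_model> ", x$label, ": ", length(x$grid), " points, ",
      x$grid_start_nm, "-", x$grid_end_nm, " nm, FWHM ",
      x$lineshape_fwhm_nm, " nm, noise SD ", x$noise_sd_absorbance,
      " AU\n", sep = "")
  invisible(x)
}

#' Benchtop scanning-monochromator instrument model
#'
#' 1100-2498 nm at a fixed 2 nm step, 2 nm line shape, 5e-4 AU noise.
#' @param ... overrides passed to [instrument_model()].
#' @return An `instrument_model`.
#' @export
foss_instrument <- function(...) {
  args <- utils::modifyList(
    list(label = "benchtop_2nm", grid_start_nm = 1100, grid_end_nm = 2498,
         step_nm = 2, lineshape_fwhm_nm = 2, noise_sd_absorbance = 5e-4),
    list(...))
  do.call(instrument_model, args)
}

#' Handheld Fourier-transform instrument model
#'
#' 1350-2550 nm at a variable step growing from 2.5 to 8.8 nm, 16 nm
#' wavelength resolution, 2e-3 AU noise (the photometric noise of such
#' handhelds is not well characterized publicly; this default is a
#' documented, adjustable guess).
#' @param ... overrides passed to [instrument_model()].
#' @return An `instrument_model`.
#' @export
neo_instrument <- function(...) {
  args <- utils::modifyList(
    list(label = "handheld_16nm", grid_start_nm = 1350, grid_end_nm = 2550,
         step_range_nm = c(2.5, 8.8), lineshape_fwhm_nm = 16,
         noise_sd_absorbance = 2e-3),
    list(...))
  do.call(instrument_model, args)
}

#' Build a constituent absorptivity library
#'
#' Each constituent receives `n_bands` Gaussian absorption bands with
#' random centers (within 1350-2498 nm), widths (SD 15-50 nm) and heights,
#' all deterministic functions of the seed. Band heights are normalized so
#' the total height is `height_scale / nominal_sd[k]` absorbance per % DM:
#' constituents with a small concentration spread get proportionally
#' stronger bands, so every constituent imprints a comparable share of
#' spectral variance -- as the major constituents of real forage do.
#'
#' @param seed RNG seed; same seed, same library.
#' @param n_bands_per_constituent Gaussian bands per constituent (>= 1).
#' @param constituents constituent names.
#' @param nominal_sd named nominal concentration SDs used for the height
#'   normalization (defaults to the packaged calibration-set SDs).
#' @param baseline numeric `c(intercept, slope)` of the shared absorbance
#'   baseline, evaluated against wavelength normalized to \[0, 1\] over
#'   1100-2550 nm.
#' @param height_scale total band height times nominal SD (AU per % DM).
#' @return An object of class `constituent_library`.
#' @export
make_library <- function(seed = 1, n_bands_per_constituent = 4,
                         constituents = forage_constituent_stats()$constituent,
                         nominal_sd = NULL, baseline = c(0.35, 0.15),
                         height_scale = 3) {
  stopifnot(n_bands_per_constituent >= 1)
  if (is.null(nominal_sd)) {
    stats <- forage_constituent_stats()
    nominal_sd <- stats::setNames(stats$sd, stats$constituent)
  }
  nominal_sd <- nominal_sd[constituents]
  if (anyNA(nominal_sd)) stop("nominal_sd must cover every constituent")
  bands <- with_seed(seed, {
    lapply(stats::setNames(constituents, constituents), function(k) {
      h <- stats::runif(n_bands_per_constituent, 0.5, 1)
      data.frame(center = stats::runif(n_bands_per_constituent, 1350, 2498),
                 width = stats::runif(n_bands_per_constituent, 25, 70),
                 height = h / sum(h) * height_scale / nominal_sd[[k]])
    })
  })
  structure(list(bands = bands, baseline = baseline,
                 range = c(1100, 2550), seed = seed,
                 n_bands = n_bands_per_constituent),
            class = "constituent_library")
}

#' Evaluate constituent absorptivity curves
#'
#' @param lib a `constituent_library`.
#' @param wavelengths_nm wavelengths to evaluate at.
#' @return Matrix (constituents x wavelengths) of absorptivities,
#'   absorbance per % DM.
#' @export
library_curves <- function(lib, wavelengths_nm) {
  wl <- as.numeric(wavelengths_nm)
  E <- matrix(0, length(lib$bands), length(wl),
              dimnames = list(names(lib$bands), NULL))
  for (k in seq_along(lib$bands)) {
    b <- lib$bands[[k]]
    for (i in seq_len(nrow(b))) {
      E[k, ] <- E[k, ] +
        b$height[i] * exp(-(wl - b$center[i])^2 / (2 * b$width[i]^2))
    }
  }
  E
}

#' True mixture absorbance of samples
#'
#' Beer-Lambert: `A(lambda) = sum_k c_k * eps_k(lambda) / 100 +
#' baseline(lambda)`.
#'
#' @param lib a `constituent_library`.
#' @param conc concentration matrix (samples x constituents, % DM) or a
#'   named vector for one sample.
#' @param wavelengths_nm wavelengths to evaluate at.
#' @param include_baseline add the library's shared baseline.
#' @return Matrix (samples x wavelengths) of absorbance.
#' @export
library_absorbance <- function(lib, conc, wavelengths_nm,
                               include_baseline = TRUE) {
  if (is.null(dim(conc))) conc <- matrix(conc, 1, dimnames = list(NULL, names(conc)))
  conc <- as.matrix(conc)[, names(lib$bands), drop = FALSE]
  E <- library_curves(lib, wavelengths_nm)
  A <- conc %*% E / 100
  if (include_baseline) {
    lam <- (wavelengths_nm - 1100) / (2550 - 1100)
    A <- A + rep(lib$baseline[1] + lib$baseline[2] * lam, each = nrow(conc))
  }
  A
}

#' Define a simulation scenario
#'
#' The study conditions of the simulator: sample count, constituent
#' marginals (mean/SD truncated to min/max), between-constituent
#' correlations, species fractions, harvest-date structure and seeds.
#' Defaults emulate a mixed alfalfa/grass database of 384 samples whose
#' odd harvest dates form a 100-sample validation partition, with the
#' packaged calibration-set marginals and laboratory errors.
#'
#' @param n_samples total samples to draw.
#' @param stats data frame in the [forage_constituent_stats()] schema.
#' @param correlations PSD correlation matrix over the constituents.
#' @param alfalfa_fraction fraction of samples labelled alfalfa.
#' @param harvest_date_count number of distinct harvest dates; odd dates
#'   are cycled over validation samples, even dates over calibration.
#' @param validation_fraction fraction of samples placed on odd harvest
#'   dates (the held-out partition of [split_by_harvest()]).
#' @param n_bands Gaussian bands per constituent in the library.
#' @param seed master seed; the library, concentration, acquisition and
#'   laboratory-noise streams use fixed offsets from it.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_samples = 384,
                         stats = forage_constituent_stats(),
                         correlations = default_correlations(),
                         alfalfa_fraction = 104 / 384,
                         harvest_date_count = 8,
                         validation_fraction = 100 / 384,
                         n_bands = 4, seed = 1234) {
  stopifnot(n_samples >= 2, harvest_date_count >= 2,
            validation_fraction > 0, validation_fraction < 1)
  nm <- stats$constituent
  correlations <- correlations[nm, nm]
  if (max(abs(correlations - t(correlations))) > 1e-8)
    stop("correlation matrix must be symmetric")
  if (min(eigen(correlations, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8)
    stop("correlation matrix must be positive semi-definite")
  structure(list(n_samples = as.integer(n_samples), stats = stats,
                 correlations = correlations,
                 alfalfa_fraction = alfalfa_fraction,
                 harvest_date_count = as.integer(harvest_date_count),
                 validation_fraction = validation_fraction,
                 n_bands = as.integer(n_bands),
                 seeds = list(library = seed, concentrations = seed + 1,
                              acquisition = seed + 2, lab = seed + 3)),
            class = "sim_scenario")
}

#' Read a simulation scenario from YAML
#'
#' Top-level keys mirror the [sim_scenario()] arguments; `stats` is a list
#' of per-constituent blocks with `min`, `mean`, `max`, `sd`, `sel`;
#' `correlations` (optional) is a list of rows. Omitted keys keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return A `sim_scenario`.
#' @export
scenario_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("n_samples", "alfalfa_fraction", "harvest_date_count",
              "validation_fraction", "n_bands", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$stats)) {
    args$stats <- do.call(rbind, lapply(names(y$stats), function(k) {
      data.frame(constituent = k, min = y$stats[[k]]$min,
                 mean = y$stats[[k]]$mean, max = y$stats[[k]]$max,
                 sd = y$stats[[k]]$sd, sel = y$stats[[k]]$sel)
    }))
  }
  if (!is.null(y$correlations)) {
    R <- do.call(rbind, y$correlations)
    nm <- if (!is.null(args$stats)) args$stats$constituent else
      forage_constituent_stats()$constituent
    dimnames(R) <- list(nm, nm)
    args$correlations <- R
  }
  do.call(sim_scenario, args)
}

# Spread k of n positions evenly through 1..n (deterministic interleave).
spread_positions <- function(n, k) {
  which(ceiling(seq_len(n) * k / n) > ceiling((seq_len(n) - 1) * k / n))
}

# Mean and SD of a Normal(mu, s) truncated to [lo, hi], closed form.
truncnorm_moments <- function(mu, s, lo, hi) {
  if (s <= 0) return(c(mu, 0))
  a <- (lo - mu) / s
  b <- (hi - mu) / s
  Z <- stats::pnorm(b) - stats::pnorm(a)
  dz <- (stats::dnorm(a) - stats::dnorm(b)) / Z
  v <- s^2 * (1 + (a * stats::dnorm(a) - b * stats::dnorm(b)) / Z - dz^2)
  c(mu + s * dz, sqrt(max(v, 0)))
}

# Parent (mu, sigma) whose [lo, hi]-truncation has the target mean and SD.
# Truncation shrinks moments, so drawing at the target parameters would
# undershoot the spread; this inverts that. A box can cap the attainable
# SD at (hi - lo) / sqrt(12) (the uniform limit); when the target exceeds
# what a truncated normal can reach, the closest attainable solution is
# returned (parent sigma bounded at twice the box width).
match_truncnorm <- function(target_mean, target_sd, lo, hi) {
  if (target_sd <= 0) return(c(mu = target_mean, sigma = 0))
  obj <- function(p) {
    m <- truncnorm_moments(p[1], exp(p[2]), lo, hi)
    (m[1] - target_mean)^2 / target_sd^2 + (m[2] - target_sd)^2 / target_sd^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "L-BFGS-B",
                      lower = c(lo - (hi - lo), log(target_sd / 10)),
                      upper = c(hi + (hi - lo), log(2 * (hi - lo))))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Draw true constituent concentrations and sample metadata
#'
#' Concentrations come from a Gaussian copula: a multivariate normal with
#' the scenario's correlation matrix supplies the dependence, and each
#' margin is mapped through the quantile function of a normal truncated to
#' the constituent's \[min, max\] box, with parent parameters
#' moment-matched so the truncated margin reproduces the scenario's mean
#' and SD (a box can cap the attainable SD at its uniform limit
#' `(max - min) / sqrt(12)`; tighter targets converge to that limit).
#' Harvest dates: `round(validation_fraction * n)`
#' samples are interleaved evenly through the dataset and cycled over the
#' odd harvest dates; the rest cycle over even dates -- emulating a
#' database whose odd harvest dates hold out roughly a quarter of the
#' samples. Species labels are interleaved by `alfalfa_fraction`.
#'
#' @param scenario a [sim_scenario()].
#' @return List with `reference` (a [reference_table()] of true values,
#'   with the scenario SELs attached) and `meta` (a [sample_meta()]).
#' @export
sample_constituents <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  st <- scenario$stats
  n <- scenario$n_samples
  lo <- st$min; hi <- st$max
  # parent parameters chosen so the box-truncated marginals hit the target
  # means/SDs (truncation would otherwise shrink both)
  parent <- vapply(seq_len(nrow(st)), function(i) {
    match_truncnorm(st$mean[i], st$sd[i], lo[i], hi[i])
  }, numeric(2))
  z <- with_seed(scenario$seeds$concentrations,
                 MASS::mvrnorm(n, rep(0, nrow(st)), scenario$correlations))
  if (n == 1) z <- matrix(z, 1)
  conc <- vapply(seq_len(nrow(st)), function(i) {
    mu <- parent[1, i]; s <- parent[2, i]
    if (s <= 0) return(rep(mu, n))
    pa <- stats::pnorm((lo[i] - mu) / s)
    pb <- stats::pnorm((hi[i] - mu) / s)
    u <- pa + stats::pnorm(z[, i]) * (pb - pa)
    pmin(pmax(mu + s * stats::qnorm(u), lo[i]), hi[i])
  }, numeric(n))
  if (n == 1) conc <- matrix(conc, 1)
  colnames(conc) <- st$constituent
  ids <- sprintf("S%04d", seq_len(n))
  n_val <- round(scenario$validation_fraction * n)
  val_pos <- spread_positions(n, n_val)
  odd_pool <- seq(1, scenario$harvest_date_count, by = 2)
  even_pool <- seq(2, scenario$harvest_date_count, by = 2)
  dates <- integer(n)
  dates[val_pos] <- odd_pool[(seq_along(val_pos) - 1) %% length(odd_pool) + 1]
  cal_pos <- setdiff(seq_len(n), val_pos)
  dates[cal_pos] <- even_pool[(seq_along(cal_pos) - 1) %% length(even_pool) + 1]
  alf_pos <- spread_positions(n, round(scenario$alfalfa_fraction * n))
  species <- rep("grass", n)
  species[alf_pos] <- "alfalfa"
  sel <- stats::setNames(st$sel, st$constituent)
  list(reference = reference_table(ids, conc, sel),
       meta = sample_meta(ids, species, dates))
}

#' Render reflectance spectra for one instrument
#'
#' The forward model: true mixture absorbance on a fine 1 nm grid,
#' per-sample multiplicative/additive scatter, convolution with the
#' instrument's Gaussian line shape, sampling onto the instrument grid,
#' iid photometric noise, and conversion to reflectance `R = 10^-A`
#' (clipped to \[1e-6, 1.5\]).
#'
#' @param truth a [reference_table()] of true concentrations.
#' @param lib a [make_library()] result covering the same constituents.
#' @param instrument an [instrument_model()].
#' @param seed RNG seed for scatter and noise.
#' @return A reflectance [spectra_set()] on the instrument grid.
#' @export
render_spectra <- function(truth, lib, instrument, seed = 1) {
  stopifnot(inherits(truth, "reference_table"),
            inherits(lib, "constituent_library"),
            inherits(instrument, "instrument_model"))
  if (!all(names(lib$bands) %in% colnames(truth$constituents)))
    stop("library constituents missing from the reference table")
  sd_nm <- instrument$lineshape_fwhm_nm / (2 * sqrt(2 * log(2)))
  half <- ceiling(4 * sd_nm)
  fine <- seq(floor(min(instrument$grid)) - half - 1,
              ceiling(max(instrument$grid)) + half + 1, by = 1)
  A <- library_absorbance(lib, truth$constituents, fine)
  n <- nrow(A)
  obs <- with_seed(seed, {
    m <- stats::rnorm(n, 1, instrument$scatter_mult_sd)
    o <- stats::rnorm(n, 0, instrument$scatter_add_sd)
    A <- A * m + o
    # Gaussian line shape on the 1 nm grid
    off <- -half:half
    k <- exp(-off^2 / (2 * sd_nm^2))
    k <- k / sum(k)
    valid <- (half + 1):(length(fine) - half)
    Ac <- matrix(0, n, length(valid))
    for (j in seq_along(off)) {
      Ac <- Ac + k[j] * A[, valid + off[j], drop = FALSE]
    }
    wl_valid <- fine[valid]
    j <- findInterval(instrument$grid, wl_valid, rightmost.closed = TRUE)
    j <- pmin(pmax(j, 1), length(wl_valid) - 1)
    w <- (instrument$grid - wl_valid[j]) / (wl_valid[j + 1] - wl_valid[j])
    Ag <- Ac[, j, drop = FALSE] * (1 - rep(w, each = n)) +
      Ac[, j + 1, drop = FALSE] * rep(w, each = n)
    Ag + matrix(stats::rnorm(length(Ag), 0, instrument$noise_sd_absorbance),
                n)
  })
  R <- pmin(pmax(10^(-obs), 1e-6), 1.5)
  spectra_set(R, instrument$grid, truth$sample_ids, "reflectance",
              instrument$label)
}

#' Add laboratory measurement noise to true constituent values
#'
#' `observed = truth + Normal(0, SEL_k)` independently per constituent,
#' emulating replicate error of the reference assays.
#'
#' @param truth a [reference_table()] of true values.
#' @param sel named SEL vector; defaults to the table's own.
#' @param seed RNG seed.
#' @return A [reference_table()] of observed values, same ids and SELs.
#' @export
add_lab_noise <- function(truth, sel = truth$sel, seed = 1) {
  stopifnot(inherits(truth, "reference_table"))
  if (is.null(sel)) stop("sel must be supplied or stored on the table")
  sel <- sel[colnames(truth$constituents)]
  if (anyNA(sel) || any(sel <= 0)) stop("sel must be positive for every constituent")
  obs <- with_seed(seed, {
    truth$constituents +
      vapply(sel, function(s) stats::rnorm(nrow(truth$constituents), 0, s),
             numeric(nrow(truth$constituents)))
  })
  reference_table(truth$sample_ids, obs, truth$sel)
}

#' Generate a complete paired two-instrument dataset
#'
#' Draws one set of true concentrations and renders it on both the 2 nm
#' benchtop-like and 16 nm handheld-like instruments (same true absorbance
#' per sample, independent scatter and noise), plus laboratory-noised
#' reference values. Fully determined by the scenario's seeds.
#'
#' @param scenario a [sim_scenario()].
#' @param foss,neo the two [instrument_model()]s.
#' @return A list of class `forage_sim`: `foss`/`neo` (reflectance
#'   [spectra_set()]s), `truth` and `observed` ([reference_table()]s),
#'   `meta` ([sample_meta()]), `library`, `scenario`.
#' @export
make_dataset <- function(scenario = sim_scenario(),
                         foss = foss_instrument(), neo = neo_instrument()) {
  lib <- make_library(scenario$seeds$library, scenario$n_bands,
                      constituents = scenario$stats$constituent,
                      nominal_sd = stats::setNames(scenario$stats$sd,
                                                   scenario$stats$constituent))
  drawn <- sample_constituents(scenario)
  foss_s <- render_spectra(drawn$reference, lib, foss,
                           seed = scenario$seeds$acquisition)
  neo_s <- render_spectra(drawn$reference, lib, neo,
                          seed = scenario$seeds$acquisition + 1)
  observed <- add_lab_noise(drawn$reference, seed = scenario$seeds$lab)
  structure(list(foss = foss_s, neo = neo_s, truth = drawn$reference,
                 observed = observed, meta = drawn$meta, library = lib,
                 scenario = scenario),
            class = "forage_sim")
}

#' @exportS3Method base::print
print.forage_sim <- function(x, ...) {
  cat("<forage_sim> ", length(x$truth$sample_ids), " samples; instruments: ",
      x$foss$instrument_label, " (", length(x$foss$wavelengths_nm),
      " pts), ", x$neo$instrument_label, " (",
      length(x$neo$wavelengths_nm), " pts)\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset as the five-CSV on-disk layout
#'
#' @param dataset a `forage_sim` from [make_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "forage_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_spectra(dataset$foss, file.path(dir, "spectra_foss.csv"))
  write_spectra(dataset$neo, file.path(dir, "spectra_neo.csv"))
  write_reference(dataset$observed, file.path(dir, "reference.csv"),
                  file.path(dir, "sel.csv"))
  write_reference(dataset$truth, file.path(dir, "reference_truth.csv"))
  write_meta(dataset$meta, file.path(dir, "meta.csv"))
  invisible(dir)
}
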