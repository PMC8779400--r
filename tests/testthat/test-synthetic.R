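# One moderately large draw shared by the marginal-fidelity checks.
big_draw <- NULL
get_big_draw <- function() {
  if (is.null(big_draw))
    big_draw <<- sample_constituents(sim_scenario(n_samples = 5000, seed = 77))
  big_draw
}

test_that("the constituent library is deterministic and Gaussian in shape", {
  l1 <- make_library(seed = 3)
  l2 <- make_library(seed = 3)
  expect_identical(l1$bands, l2$bands)
  expect_false(identical(l1$bands, make_library(seed = 4)$bands))
  # single band: value at center is the height, center +/- 1 SD is height*exp(-1/2)
  lib <- make_library(seed = 5, n_bands_per_constituent = 1,
                      constituents = "X", nominal_sd = c(X = 1),
                      baseline = c(0, 0), height_scale = 1)
  b <- lib$bands$X
  expect_equal(nrow(b), 1)
  ev <- library_curves(lib, c(b$center, b$center + b$width, b$center - b$width))
  expect_equal(unname(ev[1, 1]), b$height, tolerance = 1e-12)
  expect_equal(unname(ev[1, 2]), b$height * exp(-0.5), tolerance = 1e-12)
  expect_equal(unname(ev[1, 3]), b$height * exp(-0.5), tolerance = 1e-12)
  expect_true(all(library_curves(make_library(1), seq(1100, 2550, 10)) >= 0))
  # Beer-Lambert: absorbance at the band center is conc * height / 100
  A <- library_absorbance(lib, c(X = 50), b$center, include_baseline = FALSE)
  expect_equal(unname(A[1, 1]), 50 * b$height / 100, tolerance = 1e-12)
})

test_that("simulated concentrations reproduce the target marginals", {
  d <- get_big_draw()
  conc <- d$reference$constituents
  st <- forage_constituent_stats()
  expect_equal(unname(colMeans(conc)["NDF"]), 87, tolerance = 0.5 / 87)
  expect_equal(unname(apply(conc, 2, sd)["ADL"]), 1.2, tolerance = 0.15 / 1.2)
  # every constituent within 5 SE of the moment-matched attainable
  # marginal (identical to the target unless the [min, max] box caps the
  # reachable SD, as it does for IVTD and ADF)
  n <- nrow(conc)
  for (i in seq_len(nrow(st))) {
    k <- st$constituent[i]
    par <- foragenirs:::match_truncnorm(st$mean[i], st$sd[i],
                                        st$min[i], st$max[i])
    mm <- foragenirs:::truncnorm_moments(par[["mu"]], par[["sigma"]],
                                         st$min[i], st$max[i])
    expect_lt(abs(mean(conc[, k]) - mm[1]), 5 * st$sd[i] / sqrt(n))
    expect_lt(abs(sd(conc[, k]) - mm[2]), 5 * st$sd[i] / sqrt(2 * n))
    expect_lt(abs(mean(conc[, k]) - st$mean[i]),
              5 * st$sd[i] / sqrt(n) + abs(mm[1] - st$mean[i]))
    expect_gte(min(conc[, k]), st$min[i])
    expect_lte(max(conc[, k]), st$max[i])
  }
})

test_that("zero-SD scenarios collapse to the mean", {
  st <- forage_constituent_stats()
  st$sd <- rep(0, nrow(st))
  d <- sample_constituents(sim_scenario(n_samples = 20, stats = st, seed = 1))
  expect_equal(unname(apply(d$reference$constituents, 2, sd)),
               rep(0, nrow(st)))
  expect_equal(unname(colMeans(d$reference$constituents)), st$mean)
})

test_that("harvest dates yield the configured calibration/validation sizes", {
  d <- sample_constituents(sim_scenario(seed = 2))
  spl <- split_by_harvest(d$meta)
  expect_length(spl$calibration, 284)
  expect_length(spl$validation, 100)
  expect_setequal(c(spl$calibration, spl$validation), d$meta$id)
  expect_equal(sum(d$meta$species == "alfalfa"), 104)
  # both species present in both partitions
  for (part in spl) {
    expect_gt(length(unique(d$meta$species[d$meta$id %in% part])), 1)
  }
})

test_that("laboratory noise has the stated spread", {
  d <- get_big_draw()
  obs <- add_lab_noise(d$reference, seed = 9)
  delta <- obs$constituents - d$reference$constituents
  expect_equal(sd(delta[, "NDF"]), 0.45, tolerance = 0.1)
  # SEL -> 0 limit: observed equals truth
  tiny <- add_lab_noise(d$reference,
                        sel = setNames(rep(1e-9, 6),
                                       colnames(d$reference$constituents)),
                        seed = 9)
  expect_lt(max(abs(tiny$constituents - d$reference$constituents)), 1e-7)
  # empirical ceiling matches the closed form
  sdl <- sd(obs$constituents[, "NDF"])
  expect_equal(r2(d$reference$constituents[, "NDF"], obs$constituents[, "NDF"]),
               r2max(sdl, 0.45), tolerance = 0.01)
})

test_that("rendering reduces to R = 1 for blank samples", {
  lib <- make_library(seed = 5, constituents = "X", nominal_sd = c(X = 1),
                      baseline = c(0, 0))
  truth <- reference_table(c("a", "b"), cbind(X = c(0, 0)))
  inst <- instrument_model("t", 1400, 1500, step_nm = 2,
                           lineshape_fwhm_nm = 4, noise_sd_absorbance = 0,
                           scatter_mult_sd = 0, scatter_add_sd = 0)
  s <- render_spectra(truth, lib, inst, seed = 1)
  expect_equal(unname(s$signal), matrix(1, 2, length(inst$grid)))
})

test_that("the line shape widens bands by Gaussian convolution", {
  lib <- make_library(seed = 5, constituents = "X", nominal_sd = c(X = 1),
                      baseline = c(0, 0), n_bands_per_constituent = 1)
  lib$bands$X <- data.frame(center = 1900, width = 20, height = 1)
  truth <- reference_table("a", cbind(X = 80))
  inst <- instrument_model("t", 1600, 2200, step_nm = 1,
                           lineshape_fwhm_nm = 16, noise_sd_absorbance = 0,
                           scatter_mult_sd = 0, scatter_add_sd = 0)
  s <- render_spectra(truth, lib, inst, seed = 1)
  A <- -log10(s$signal[1, ])
  half <- max(A) / 2
  above <- which(A >= half)
  lo <- approx(A[c(min(above) - 1, min(above))],
               inst$grid[c(min(above) - 1, min(above))], xout = half)$y
  hi <- approx(A[c(max(above), max(above) + 1)],
               inst$grid[c(max(above), max(above) + 1)], xout = half)$y
  expected <- sqrt((2 * sqrt(2 * log(2)) * 20)^2 + 16^2)
  expect_equal(hi - lo, expected, tolerance = 0.02)
})

test_that("wider line shapes never move the spectrum closer to the truth", {
  lib <- make_library(seed = 6)
  truth <- sample_constituents(sim_scenario(n_samples = 5, seed = 3))$reference
  base_inst <- function(f) instrument_model("t", 1400, 2400, step_nm = 2,
                                            lineshape_fwhm_nm = f,
                                            noise_sd_absorbance = 0,
                                            scatter_mult_sd = 0,
                                            scatter_add_sd = 0)
  narrow <- render_spectra(truth, lib, base_inst(0.5), seed = 1)
  rms <- vapply(c(2, 8, 16, 32), function(f) {
    s <- render_spectra(truth, lib, base_inst(f), seed = 1)
    sqrt(mean((-log10(s$signal) + log10(narrow$signal))^2))
  }, numeric(1))
  expect_true(all(diff(rms) >= 0))
})

test_that("paired datasets are reproducible and the handheld grid coarsens", {
  sc <- sim_scenario(n_samples = 24, seed = 11)
  d1 <- make_dataset(sc)
  d2 <- make_dataset(sc)
  expect_identical(d1$foss$signal, d2$foss$signal)
  expect_identical(d1$neo$signal, d2$neo$signal)
  expect_identical(d1$observed$constituents, d2$observed$constituents)
  g <- d1$neo$wavelengths_nm
  expect_gte(min(g), 1350)
  expect_lte(max(g), 2550)
  steps <- diff(g)
  expect_true(all(steps > 0))
  expect_equal(steps[1], 2.5, tolerance = 0.01)
  expect_equal(steps[length(steps)], 8.8, tolerance = 0.01)
  # identical instrument models produce identical matrices when noise-free
  quiet <- instrument_model("q", 1400, 2400, step_nm = 2,
                            lineshape_fwhm_nm = 4, noise_sd_absorbance = 0,
                            scatter_mult_sd = 0, scatter_add_sd = 0)
  d3 <- make_dataset(sc, foss = quiet, neo = quiet)
  expect_equal(d3$foss$signal, d3$neo$signal, tolerance = 1e-12)
})
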