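test_that("absorbance conversion is log10(1/R)", {
  s <- spectra_set(matrix(c(1, 0.1, 0.5), 1), c(1400, 1402, 1404), "a")
  a <- to_absorbance(s)
  expect_equal(unname(a$signal[1, ]), c(0, 1, log10(2)), tolerance = 1e-12)
  expect_identical(a$signal_kind, "absorbance")
  expect_identical(to_absorbance(a), a)  # no double conversion
})

test_that("SNV standardizes rows and ignores offset and positive scale", {
  s <- spectra_set(matrix(c(1, 2, 3), 1), c(1400, 1402, 1404), "a",
                   signal_kind = "absorbance")
  expect_equal(unname(snv(s)$signal[1, ]), c(-1, 0, 1))
  r <- random_spectra(n = 4, p = 20, seed = 5, kind = "absorbance")
  out <- snv(r)
  expect_equal(unname(rowMeans(out$signal)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(out$signal, 1, sd)), rep(1, 4), tolerance = 1e-12)
  scaled <- r
  scaled$signal <- 3.7 * r$signal + 0.9
  expect_equal(snv(scaled)$signal, out$signal, tolerance = 1e-12)
  const <- spectra_set(matrix(1, 1, 3), c(1, 2, 3), "a", "absorbance")
  expect_error(snv(const), "constant")
})

test_that("detrend removes polynomials and matches a least-squares oracle", {
  wl <- seq(1400, by = 2, length.out = 30)
  quad <- 2 + 0.01 * wl - 1e-5 * wl^2
  s <- spectra_set(rbind(quad), wl, "a", "absorbance")
  expect_lt(max(abs(detrend(s, 2)$signal)), 1e-9)
  r <- random_spectra(n = 3, p = 30, seed = 8, kind = "absorbance", wl = wl)
  d <- detrend(r, 2)
  # residuals orthogonal to {1, wl, wl^2}
  B <- cbind(1, wl, wl^2)
  expect_lt(max(abs(d$signal %*% B)) / max(abs(r$signal %*% B)), 1e-9)
  # independent per-row lm oracle
  oracle <- t(apply(r$signal, 1, function(x) residuals(lm(x ~ wl + I(wl^2)))))
  expect_equal(unname(d$signal), unname(oracle), tolerance = 1e-9)
})

test_that("Savitzky-Golay is exact on polynomials and drops edges", {
  i <- seq_len(60)
  row <- 0.3 + 0.012 * i - 2e-4 * i^2
  s <- spectra_set(rbind(row), 1398 + 2 * i, "a", "absorbance")
  sm <- savitzky_golay(s, 11, 2, 0)
  expect_equal(ncol(sm$signal), 60 - 10)  # (window-1)/2 dropped per side
  expect_equal(sm$wavelengths_nm, s$wavelengths_nm[6:55])
  expect_lt(max(abs(sm$signal[1, ] - row[6:55])), 1e-9)
  d1 <- savitzky_golay(s, 11, 2, 1)
  expect_lt(max(abs(d1$signal[1, ] - (0.012 - 4e-4 * i[6:55]))), 1e-9)
  lin <- spectra_set(rbind(1 + 0.02 * i), 1398 + 2 * i, "a", "absorbance")
  expect_lt(max(abs(savitzky_golay(lin, 15, 2, 2)$signal)), 1e-9)
  expect_error(savitzky_golay(s, 10, 2, 0), "odd")
  expect_error(savitzky_golay(s, 11, 2, 3), "deriv")
  expect_error(savitzky_golay(s[, 1:5], 11, 2, 0), "fewer channels")
})

test_that("trim keeps the closed interval and composes", {
  wl <- seq(1100, 2498, by = 2)
  s <- spectra_set(matrix(0.5, 2, length(wl)), wl, c("a", "b"))
  tr <- trim_spectra(s, 1350, 2498)
  expect_equal(ncol(tr$signal), 575)
  expect_equal(range(tr$wavelengths_nm), c(1350, 2498))
  expect_equal(trim_spectra(s, 1000, 3000)$signal, s$signal)
  expect_error(trim_spectra(s, 2000, 1000), "lo_nm < hi_nm")
  nested <- trim_spectra(trim_spectra(s, 1300, 2400), 1500, 2000)
  expect_equal(nested$wavelengths_nm, trim_spectra(s, 1500, 2000)$wavelengths_nm)
})

test_that("resampling interpolates linearly and refuses extrapolation", {
  wl <- c(1400, 1410, 1430, 1440)
  sig <- rbind(c(0.2, 0.4, 0.8, 0.6), c(0.5, 0.3, 0.1, 0.9))
  s <- spectra_set(sig, wl, c("a", "b"))
  expect_equal(resample_to_grid(s, wl)$signal, s$signal, tolerance = 1e-12)
  mid <- resample_to_grid(s, c(1405, 1420, 1435))
  expect_equal(unname(mid$signal[, 1]), unname((sig[, 1] + sig[, 2]) / 2))
  expect_equal(unname(mid$signal[, 3]), unname((sig[, 3] + sig[, 4]) / 2))
  lin <- spectra_set(rbind(0.1 + 0.001 * (wl - 1400)), wl, "a")
  at <- resample_to_grid(lin, c(1403, 1427))
  expect_equal(unname(at$signal[1, ]), 0.1 + 0.001 * c(3, 27), tolerance = 1e-12)
  expect_error(resample_to_grid(s, c(1395, 1420)), "extrapolate")
})

test_that("the preprocessing grid has the full sensitivity-space cardinality", {
  grid <- enumerate_grid()
  expect_length(grid, 122)
  labels <- vapply(grid, config_label, character(1))
  expect_false(anyDuplicated(labels) > 0)
  windows <- sort(unique(unlist(lapply(grid, function(g) g$sg$window))))
  expect_equal(windows, seq(9, 27, by = 2))
  # identical, deterministic order on re-enumeration
  expect_identical(labels, vapply(enumerate_grid(), config_label, character(1)))
  n_sg_free <- sum(vapply(grid, function(g) is.null(g$sg), logical(1)))
  expect_equal(n_sg_free, 2)
  expect_true(all(vapply(grid, function(g)
    is.null(g$sg) || g$sg$deriv <= g$sg$polyorder, logical(1))))
})

test_that("preprocess_train centers on training data only", {
  s <- random_spectra(n = 10, p = 20, seed = 13)
  cfg <- preprocess_config("none")
  pp <- preprocess_train(cfg, s[1:6, ])
  expect_equal(unname(colMeans(pp$spectra$signal)), rep(0, 20),
               tolerance = 1e-12)
  ev <- preprocess_apply(pp, s[7:10, ])
  expect_gt(max(abs(colMeans(ev$signal))), 1e-4)  # training means reapplied
  expect_identical(ev$sample_ids, s$sample_ids[7:10])
  # all-off recipe is absorbance + centering only
  manual <- to_absorbance(s[1:6, ])$signal
  manual <- manual - rep(colMeans(manual), each = 6)
  expect_equal(pp$spectra$signal, manual, tolerance = 1e-12)
  # idempotent centering: retraining on the centered output changes nothing
  cfg2 <- preprocess_config("none")
  pp2 <- preprocess_train(cfg2, pp$spectra)
  expect_equal(pp2$spectra$signal, pp$spectra$signal, tolerance = 1e-12)
  # grid mismatch is refused
  expect_error(preprocess_apply(pp, s[7:10, 1:10]), "grid")
})

test_that("non-uniform grids are resampled to 2 nm before Savitzky-Golay", {
  set.seed(21)
  wl <- cumsum(c(1400, runif(79, 2, 6)))
  s <- spectra_set(matrix(runif(160, 0.3, 0.7), 2), wl, c("a", "b"))
  cfg <- preprocess_config("none", sg = list(window = 9, polyorder = 2,
                                             deriv = 1))
  pp <- preprocess_train(cfg, s)
  expect_equal(unique(round(diff(pp$wavelengths_nm), 9)), 2)
})
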