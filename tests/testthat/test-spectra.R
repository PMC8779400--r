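test_that("spectra write/read round trip is the identity to 1e-9", {
  s <- random_spectra(n = 6, p = 11, seed = 42)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(s, path)
  s2 <- read_spectra(path, "reflectance")
  expect_identical(s2$sample_ids, s$sample_ids)
  expect_equal(s2$wavelengths_nm, s$wavelengths_nm)
  expect_lt(max(abs(s2$signal - s$signal)), 1e-9)
})

test_that("degenerate spectra files round-trip", {
  empty <- spectra_set(matrix(0.5, 0, 3), c(1400, 1402, 1404), character(0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(empty, path)
  expect_length(readLines(path), 1)  # header only
  one <- spectra_set(matrix(0.5, 1, 1), 1500, "a")
  write_spectra(one, path)
  expect_length(readLines(path), 2)
  back <- read_spectra(path, "reflectance")
  expect_equal(back$signal[1, 1], 0.5)
})

test_that("spectra constructor and reader reject malformed input", {
  expect_error(spectra_set(matrix(0.5, 2, 2), c(2498, 1350), c("a", "b")),
               "increasing")
  expect_error(spectra_set(matrix(0.5, 2, 2), c(1350, 2498), c("a", "a")),
               "duplicate")
  expect_error(spectra_set(matrix(c(0.5, -0.1, 0.4, 0.3), 2, 2),
                           c(1350, 2498), c("a", "b")), "positive")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,2498,1350", "a,0.5,0.6"), path)
  expect_error(read_spectra(path, "reflectance"), "increasing")
  writeLines(c("id,1350,2498", "a,0.5,oops"), path)
  expect_error(read_spectra(path, "reflectance"), "non-numeric")
  writeLines(c("id,1350,2498", "a,0.5,0.6", "a,0.4,0.3"), path)
  expect_error(read_spectra(path, "reflectance"), "duplicate")
})

test_that("reference table enforces its invariants", {
  vals <- cbind(NDF = c(80, 90), CP = c(15, 25))
  r <- reference_table(c("a", "b"), vals, c(NDF = 0.45, CP = 0.21))
  expect_equal(r$sel[["CP"]], 0.21)
  expect_error(reference_table(c("a", "b"), vals, c(NDF = 0, CP = 0.21)),
               "positive")
  expect_error(reference_table(c("a", "b"),
                               cbind(NDF = c(80, 101), CP = c(15, 25))),
               "0, 100")
  expect_error(reference_table(c("a", "a"), vals), "duplicate")
})

test_that("alignment restricts to shared ids in spectra order and is idempotent", {
  s <- random_spectra(n = 3, seed = 9)
  s$sample_ids <- c("a", "b", "c")
  rownames(s$signal) <- s$sample_ids
  r <- reference_table(c("b", "c", "d"), cbind(NDF = c(80, 85, 90)))
  m <- sample_meta(c("c", "b", "e"), c("grass", "alfalfa", "grass"), c(1, 2, 3))
  al <- align_dataset(s, r, m)
  expect_identical(al$spectra$sample_ids, c("b", "c"))
  expect_identical(al$reference$sample_ids, c("b", "c"))
  expect_identical(al$meta$id, c("b", "c"))
  expect_setequal(al$dropped, c("a", "d", "e"))
  al2 <- align_dataset(al$spectra, al$reference, al$meta)
  expect_identical(al2$spectra$signal, al$spectra$signal)
  expect_identical(al2$reference$constituents, al$reference$constituents)
  r_disjoint <- reference_table("z", cbind(NDF = 80))
  expect_error(align_dataset(s, r_disjoint), "no sample ids")
})
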