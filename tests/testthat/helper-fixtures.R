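# Shared fixtures, built in code.

# Small random spectra set on a uniform grid.
random_spectra <- function(n = 5, p = 8, seed = 1, kind = "reflectance",
                           wl = seq(1400, by = 2, length.out = p)) {
  set.seed(seed)
  sig <- matrix(runif(n * p, 0.2, 0.9), n, p)
  if (kind == "absorbance") sig <- -log10(sig)
  spectra_set(sig, wl, sprintf("s%02d", seq_len(n)), kind)
}

# A noiseless, scatter-free rank-controlled dataset: y is an exact linear
# function of the spectra, so a 1-LV PLS fits it perfectly.
exact_rank_data <- function(n = 40, p = 30, seed = 3) {
  set.seed(seed)
  tvec <- rnorm(n)
  pvec <- rnorm(p)
  X <- outer(tvec, pvec)
  list(X = X, y = 2 + 1.5 * tvec)
}

# The end-to-end study on the default scenario is expensive (minutes);
# compute it once per test run and share across files.
.study_cache <- new.env(parent = emptyenv())

cached_default_dataset <- function() {
  if (is.null(.study_cache$dataset))
    .study_cache$dataset <- make_dataset(sim_scenario())
  .study_cache$dataset
}

cached_default_study <- function() {
  if (is.null(.study_cache$study))
    .study_cache$study <- calibrate_and_validate(cached_default_dataset())
  .study_cache$study
}
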