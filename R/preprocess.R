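#' Convert reflectance spectra to absorbance
#'
#' Applies `A = log10(1/R)` elementwise; the wavelength grid is unchanged.
#'
#' @param s a `spectra_set` with `signal_kind = "reflectance"`.
#' @return A `spectra_set` with `signal_kind = "absorbance"`.
#' @export
to_absorbance <- function(s) {
  stopifnot(inherits(s, "spectra_set"))
  if (s$signal_kind == "absorbance") return(s)
  if (any(s$signal <= 0)) stop("reflectance must be strictly positive")
  out <- s
  out$signal <- -log10(s$signal)
  dimnames(out$signal) <- dimnames(s$signal)
  out$signal_kind <- "absorbance"
  out
}

#' Standard normal variate (SNV) scatter correction
#'
#' Standardizes each spectrum (row) to mean 0 and standard deviation 1
#' (denominator n-1). Invariant under per-spectrum offset and positive
#' scaling, which is what makes it a multiplicative-scatter correction.
#'
#' @param s a `spectra_set`.
#' @return The row-standardized `spectra_set`.
#' @export
snv <- function(s) {
  stopifnot(inherits(s, "spectra_set"))
  m <- rowMeans(s$signal)
  sd <- sqrt(rowSums((s$signal - m)^2) / (ncol(s$signal) - 1))
  if (any(sd == 0)) stop("constant spectrum: SNV undefined")
  out <- s
  out$signal <- (s$signal - m) / sd
  dimnames(out$signal) <- dimnames(s$signal)
  out
}

#' Polynomial detrend of each spectrum
#'
#' Subtracts from each row its least-squares polynomial fit against
#' wavelength. Degree 2 is the convention when paired with SNV.
#'
#' @param s a `spectra_set`.
#' @param degree polynomial degree (default 2).
#' @return The detrended `spectra_set`.
#' @export
detrend <- function(s, degree = 2) {
  stopifnot(inherits(s, "spectra_set"))
  p <- ncol(s$signal)
  if (p < degree + 1) stop("need at least degree + 1 wavelengths")
  B <- cbind(1, stats::poly(s$wavelengths_nm, degree))
  H <- B %*% solve(crossprod(B), t(B))
  out <- s
  out$signal <- s$signal - s$signal %*% H
  dimnames(out$signal) <- dimnames(s$signal)
  out
}

sg_kernel <- function(window, polyorder, deriv) {
  # central row of the Savitzky-Golay projection matrix: convolving with it
  # yields the deriv-th per-index derivative of the local LS polynomial
  signal::sgolay(p = polyorder, n = window, m = deriv)[(window + 1) / 2, ]
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Local polynomial filtering of each spectrum. Derivatives are taken with
#' respect to channel index, not nm; on a uniform grid the two differ by a
#' constant factor that is absorbed by downstream regression coefficients.
#' The `(window - 1) / 2` edge channels on each side, where the filter
#' window does not fit, are dropped and the wavelength grid shrinks
#' accordingly -- no padding is invented.
#'
#' @param s a `spectra_set`.
#' @param window odd filter length (channels), conventionally 9-27.
#' @param polyorder local polynomial order (2 or 3), `> deriv`-compatible:
#'   `deriv <= polyorder` and `window > polyorder`.
#' @param deriv derivative order: 0 (smoothing), 1 or 2.
#' @return A `spectra_set` with `ncol - window + 1` channels.
#' @export
savitzky_golay <- function(s, window, polyorder, deriv = 0) {
  stopifnot(inherits(s, "spectra_set"))
  if (window %% 2 != 1) stop("window must be odd")
  if (polyorder >= window) stop("window must exceed polyorder")
  if (deriv > polyorder) stop("deriv must not exceed polyorder")
  p <- ncol(s$signal)
  if (p < window) stop("fewer channels (", p, ") than window (", window, ")")
  k <- sg_kernel(window, polyorder, deriv)
  h <- (window - 1) / 2
  keep <- (h + 1):(p - h)
  acc <- matrix(0, nrow(s$signal), length(keep))
  for (j in seq_len(window)) {
    acc <- acc + k[j] * s$signal[, keep + j - h - 1, drop = FALSE]
  }
  out <- s
  out$signal <- acc
  out$wavelengths_nm <- s$wavelengths_nm[keep]
  dimnames(out$signal) <- list(s$sample_ids,
                               format(out$wavelengths_nm, trim = TRUE))
  out
}

#' Trim spectra to a wavelength window
#'
#' Keeps the columns with `lo_nm <= wavelength <= hi_nm` (closed interval).
#'
#' @param s a `spectra_set`.
#' @param lo_nm,hi_nm window bounds in nm, `lo_nm < hi_nm`.
#' @return The trimmed `spectra_set`.
#' @export
trim_spectra <- function(s, lo_nm, hi_nm) {
  stopifnot(inherits(s, "spectra_set"))
  if (lo_nm >= hi_nm) stop("need lo_nm < hi_nm")
  keep <- which(s$wavelengths_nm >= lo_nm & s$wavelengths_nm <= hi_nm)
  if (length(keep) == 0) stop("no wavelengths in [", lo_nm, ", ", hi_nm, "]")
  s[, keep]
}

#' Resample spectra onto a target wavelength grid
#'
#' Per-row linear interpolation. The target grid must lie within the
#' source span; extrapolation is refused.
#'
#' @param s a `spectra_set`.
#' @param target_wavelengths strictly increasing grid in nm.
#' @return A `spectra_set` on the target grid.
#' @export
resample_to_grid <- function(s, target_wavelengths) {
  stopifnot(inherits(s, "spectra_set"))
  wl <- s$wavelengths_nm
  tw <- as.numeric(target_wavelengths)
  if (min(tw) < min(wl) || max(tw) > max(wl))
    stop("target grid extends beyond source span; refusing to extrapolate")
  j <- findInterval(tw, wl, rightmost.closed = TRUE)
  j <- pmin(pmax(j, 1), length(wl) - 1)
  w <- (tw - wl[j]) / (wl[j + 1] - wl[j])
  out <- s
  out$signal <- s$signal[, j, drop = FALSE] * (1 - rep(w, each = nrow(s$signal))) +
    s$signal[, j + 1, drop = FALSE] * rep(w, each = nrow(s$signal))
  out$wavelengths_nm <- tw
  dimnames(out$signal) <- list(s$sample_ids, format(tw, trim = TRUE))
  out
}

#' Define a preprocessing recipe
#'
#' One cell of the preprocessing sensitivity grid. Transforms are always
#' applied in the fixed order: absorbance conversion, wavelength trim,
#' (resampling to a uniform grid when a Savitzky-Golay step meets a
#' non-uniform grid), SNV + detrend, Savitzky-Golay, mean-centering.
#' Centering statistics always come from a stated training set and are
#' reapplied unchanged to evaluation data.
#'
#' @param scatter `"none"` or `"snv_detrend"`.
#' @param sg `NULL`, or a list/vector with elements `window` (odd, 9-27),
#'   `polyorder` (2 or 3) and `deriv` (0, 1 or 2, at most `polyorder`).
#' @param trim length-2 numeric `c(lo_nm, hi_nm)`, or `NULL` for no trim.
#' @param to_absorbance convert reflectance to log10(1/R) first.
#' @param mean_center subtract training column means as the last step.
#' @param detrend_degree polynomial degree of the detrend step.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(scatter = c("none", "snv_detrend"), sg = NULL,
                              trim = NULL, to_absorbance = TRUE,
                              mean_center = TRUE, detrend_degree = 2) {
  scatter <- match.arg(scatter)
  if (!is.null(sg)) {
    sg <- as.list(sg)
    stopifnot(all(c("window", "polyorder", "deriv") %in% names(sg)))
    if (sg$window %% 2 != 1 || sg$window <= sg$polyorder)
      stop("sg window must be odd and exceed polyorder")
    if (!sg$polyorder %in% c(2, 3)) stop("sg polyorder must be 2 or 3")
    if (!sg$deriv %in% 0:2 || sg$deriv > sg$polyorder)
      stop("sg deriv must be 0, 1 or 2 and at most polyorder")
  }
  if (!is.null(trim)) {
    stopifnot(length(trim) == 2, trim[1] < trim[2])
  }
  structure(list(to_absorbance = to_absorbance, scatter = scatter, sg = sg,
                 trim = trim, mean_center = mean_center,
                 detrend_degree = detrend_degree),
            class = "preprocess_config")
}

#' @exportS3Method base::print
print.preprocess_config <- function(x, ...) {
  cat("<preprocess_config>", config_label(x), "\n")
  invisible(x)
}

#' One-line label for a preprocessing recipe
#' @param config a `preprocess_config`.
#' @return A character scalar such as `"snv_detrend+sg(w=11,p=2,d=1)"`.
#' @export
config_label <- function(config) {
  parts <- c(if (config$to_absorbance) "log1R",
             if (!is.null(config$trim))
               sprintf("trim(%g,%g)", config$trim[1], config$trim[2]),
             if (config$scatter != "none") config$scatter,
             if (!is.null(config$sg))
               sprintf("sg(w=%d,p=%d,d=%d)", config$sg$window,
                       config$sg$polyorder, config$sg$deriv),
             if (config$mean_center) "center")
  paste(parts, collapse = "+")
}

#' Enumerate the preprocessing sensitivity grid
#'
#' The full factorial explored when tuning a calibration: scatter
#' correction off or SNV + detrend, crossed with either no Savitzky-Golay
#' step or every combination of odd window 9-27, polynomial order 2-3 and
#' derivative order 0-2 (derivative never exceeding the polynomial order).
#' That is 2 x (1 + 10 x 6) = 122 recipes, in a fixed deterministic order.
#'
#' @param trim optional `c(lo_nm, hi_nm)` applied to every recipe.
#' @return A list of [preprocess_config()] objects.
#' @export
enumerate_grid <- function(trim = NULL) {
  grid <- list()
  for (scatter in c("none", "snv_detrend")) {
    grid[[length(grid) + 1]] <- preprocess_config(scatter, sg = NULL, trim = trim)
    for (window in seq(9, 27, by = 2)) {
      for (polyorder in 2:3) {
        for (deriv in 0:2) {
          if (deriv > polyorder) next
          grid[[length(grid) + 1]] <- preprocess_config(
            scatter, sg = list(window = window, polyorder = polyorder,
                               deriv = deriv), trim = trim)
        }
      }
    }
  }
  grid
}

is_uniform_grid <- function(wl, rel_tol = 1e-6) {
  d <- diff(wl)
  length(d) == 0 || (max(d) - min(d)) <= rel_tol * mean(d)
}

# All per-row transforms of a recipe (everything except centering).
# Row transforms use no cross-sample statistics, so they can be computed
# once for a dataset and split into folds afterwards without leakage.
row_transform <- function(config, s, uniform_step = 2) {
  if (config$to_absorbance && s$signal_kind == "reflectance")
    s <- to_absorbance(s)
  if (!is.null(config$trim))
    s <- trim_spectra(s, config$trim[1], config$trim[2])
  if (!is.null(config$sg) && !is_uniform_grid(s$wavelengths_nm)) {
    rng <- range(s$wavelengths_nm)
    s <- resample_to_grid(s, seq(rng[1], rng[2], by = uniform_step))
  }
  if (config$scatter == "snv_detrend")
    s <- detrend(snv(s), degree = config$detrend_degree)
  if (!is.null(config$sg))
    s <- savitzky_golay(s, config$sg$window, config$sg$polyorder,
                        config$sg$deriv)
  s
}

#' Fit a preprocessing recipe on training spectra
#'
#' Applies the recipe's row transforms and computes the column-mean
#' centering statistics from these (training) spectra only. The returned
#' object re-applies the identical transform, including the frozen
#' centering vector, to any evaluation spectra via [preprocess_apply()].
#'
#' @param config a [preprocess_config()].
#' @param s training `spectra_set`.
#' @return A list of class `nirs_preprocess` with elements `spectra` (the
#'   transformed training set), `center`, `wavelengths_nm`, `config`.
#' @export
preprocess_train <- function(config, s) {
  st <- row_transform(config, s)
  center <- if (config$mean_center) colMeans(st$signal) else
    rep(0, ncol(st$signal))
  st$signal <- st$signal - rep(center, each = nrow(st$signal))
  structure(list(spectra = st, center = center,
                 wavelengths_nm = st$wavelengths_nm, config = config),
            class = "nirs_preprocess")
}

#' Apply a fitted preprocessing recipe to new spectra
#'
#' @param pp a `nirs_preprocess` from [preprocess_train()].
#' @param s a `spectra_set` on the same source grid as the training data.
#' @return The transformed `spectra_set` (centered with training means, so
#'   evaluation column means are in general non-zero).
#' @export
preprocess_apply <- function(pp, s) {
  st <- row_transform(pp$config, s)
  if (length(st$wavelengths_nm) != length(pp$wavelengths_nm) ||
      max(abs(st$wavelengths_nm - pp$wavelengths_nm)) > 1e-8)
    stop("new spectra do not reduce to the training wavelength grid")
  st$signal <- st$signal - rep(pp$center, each = nrow(st$signal))
  st
}
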