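#' Split samples into calibration and validation by harvest date
#'
#' Samples from odd-numbered harvest dates form the validation set; even
#' dates form the calibration set. Done before any preprocessing or model
#' selection, so no validation information leaks into calibration.
#'
#' @param meta a [sample_meta()].
#' @return List with character vectors `calibration` and `validation`.
#' @export
split_by_harvest <- function(meta) {
  odd <- meta$harvest_date_index %% 2 == 1
  if (!any(odd)) stop("no odd harvest dates: validation partition empty")
  if (all(odd)) stop("no even harvest dates: calibration partition empty")
  list(calibration = meta$id[!odd], validation = meta$id[odd])
}

#' Venetian-blinds cross-validation fold assignment
#'
#' Sample at position `i` (dataset order, no shuffling -- the order is
#' part of the contract) is assigned to fold
#' `floor((i - 1) / thickness) mod splits + 1`: consecutive blocks of
#' `thickness` samples cycle through the folds like blind slats.
#'
#' @param n number of samples.
#' @param splits number of folds (default 5).
#' @param thickness blind thickness: consecutive samples per slat.
#' @return Integer vector of fold labels in `1..splits`.
#' @export
venetian_folds <- function(n, splits = 5, thickness = 1) {
  if (n < splits) stop("need at least as many samples as splits")
  stopifnot(splits >= 2, thickness >= 1)
  (((seq_len(n) - 1) %/% thickness) %% splits) + 1L
}

# Venetian-blinds CV of a PLS fit on an already row-transformed matrix.
# Centering (the only cross-sample statistic) is refit per fold inside
# pls_nipals, so out-of-fold predictions see training statistics only.
# Returns pooled out-of-fold predictions at each of 1..lv components.
cv_pls <- function(X, y, lv, splits = 5, thickness = 1) {
  n <- nrow(X)
  folds <- venetian_folds(n, splits, thickness)
  P_cv <- matrix(NA_real_, n, lv)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (sum(tr) < 2) stop("fold training set too small")
    k <- min(lv, sum(tr) - 1, ncol(X))
    fit <- pls_nipals(X[tr, , drop = FALSE], y[tr], ncomp = k)
    for (a in seq_len(lv)) {
      P_cv[!tr, a] <- predict(fit, X[!tr, , drop = FALSE],
                              ncomp = min(a, fit$n_lv))
    }
  }
  P_cv
}

#' Cross-validate a preprocessing recipe and latent-variable count
#'
#' Runs venetian-blinds cross-validation of the full preprocessing + PLS
#' chain: per-spectrum transforms are applied once (they use no
#' cross-sample information), while centering and the PLS factorization
#' are refit on each fold's training samples only. Pooled out-of-fold
#' predictions are scored by SECV and R2CV.
#'
#' @param s calibration `spectra_set`.
#' @param y laboratory reference values, aligned with `s`.
#' @param config a [preprocess_config()].
#' @param lv number of latent variables (from the calibration-set fit).
#' @param splits,thickness venetian-blinds parameters.
#' @param secv_df degrees of freedom for SECV: `"n_minus_1_minus_lv"`
#'   (charging for the latent variables) or `"n_minus_1"`.
#' @param all_lv also return SECV at every component count 1..lv.
#' @return List with `secv`, `r2cv`, `p_cv` (pooled out-of-fold
#'   predictions), `folds`, and when `all_lv = TRUE` also `secv_by_lv`.
#' @export
cross_validate <- function(s, y, config, lv, splits = 5, thickness = 1,
                           secv_df = c("n_minus_1_minus_lv", "n_minus_1"),
                           all_lv = FALSE) {
  secv_df <- match.arg(secv_df)
  st <- row_transform(config, s)
  X <- st$signal
  P_cv <- cv_pls(X, y, lv, splits, thickness)
  secv_at <- function(p, k) {
    if (secv_df == "n_minus_1") rmsep(y, p) else secv(y, p, k)
  }
  out <- list(secv = secv_at(P_cv[, lv], lv), r2cv = r2(y, P_cv[, lv]),
              p_cv = P_cv[, lv],
              folds = venetian_folds(nrow(X), splits, thickness))
  if (all_lv)
    out$secv_by_lv <- vapply(seq_len(lv), function(a) secv_at(P_cv[, a], a),
                             numeric(1))
  out
}

#' Search the preprocessing grid for the best calibration recipe
#'
#' For every recipe: fit PLS on the calibration set, select the number of
#' latent variables by the explained-X-variance rule, and compute SEC and
#' (venetian-blinds) SECV. The winner minimizes SECV; among recipes
#' within 1% relative SECV of that minimum, the one with the smallest
#' `|SECV - SEC|` gap wins (simultaneously minimizing the error and the
#' calibration/cross-validation gap); remaining ties break by grid order.
#'
#' @param s calibration `spectra_set`.
#' @param y laboratory reference values, aligned with `s`.
#' @param grid list of [preprocess_config()]s (e.g. [enumerate_grid()]).
#' @param splits,thickness venetian-blinds parameters.
#' @param var_threshold,min_samples_per_lv latent-variable selection rule
#'   (see [select_lvs()]).
#' @param max_lv hard upper bound on components explored.
#' @param use_overfit_guard also run [overfit_guard()] on each recipe's
#'   SECV-by-component curve (off by default).
#' @param secv_df passed to [cross_validate()].
#' @param gap_band relative SECV band within which the SEC/SECV gap
#'   decides (default 1%).
#' @return List with `best_config`, `best_index`, and `table` (one row
#'   per recipe: label, lv, sec, r2c, secv, r2cv).
#' @export
grid_search <- function(s, y, grid, splits = 5, thickness = 1,
                        var_threshold = 95, min_samples_per_lv = 10,
                        max_lv = 30, use_overfit_guard = FALSE,
                        secv_df = "n_minus_1_minus_lv", gap_band = 0.01) {
  if (length(grid) == 0) stop("empty preprocessing grid")
  n <- length(y)
  cap <- max(1L, min(floor(n / min_samples_per_lv), n - 1, max_lv))
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    config <- grid[[i]]
    res <- tryCatch({
      st <- row_transform(config, s)
      X <- st$signal
      ncomp <- min(cap, ncol(X))
      fit <- pls_nipals(X, y, ncomp = ncomp,
                        stop_at_cumvar = max(var_threshold, 95))
      k <- select_lvs(cumsum(fit$explained_x_pct), n, var_threshold,
                      min_samples_per_lv)
      cv <- cross_validate(s, y, config, k, splits, thickness, secv_df,
                           all_lv = use_overfit_guard)
      if (use_overfit_guard) {
        k2 <- overfit_guard(cv$secv_by_lv, k)
        if (k2 < k) {
          k <- k2
          cv$secv <- cv$secv_by_lv[k]
          cv$r2cv <- r2(y, cv_pls(X, y, k, splits, thickness)[, k])
        }
      }
      pc <- predict(fit, X, ncomp = k)
      data.frame(config = config_label(config), lv = k,
                 sec = sec(y, pc, k), r2c = r2(y, pc),
                 secv = cv$secv, r2cv = cv$r2cv)
    }, error = function(e) {
      data.frame(config = config_label(config), lv = NA_integer_,
                 sec = NA_real_, r2c = NA_real_, secv = NA_real_,
                 r2cv = NA_real_)
    })
    rows[[i]] <- res
  }
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$secv))
  if (length(ok) == 0) stop("every preprocessing recipe failed")
  best_secv <- min(tab$secv[ok])
  band <- ok[tab$secv[ok] <= best_secv * (1 + gap_band)]
  gaps <- abs(tab$secv[band] - tab$sec[band])
  best <- band[which.min(gaps)]
  list(best_config = grid[[best]], best_index = best, table = tab)
}

#' Fit and validate forage calibrations for one instrument
#'
#' The end-to-end pipeline: align spectra, reference values and metadata;
#' segregate the odd harvest dates as the validation partition; per
#' constituent, search the preprocessing grid on the calibration
#' partition (venetian-blinds cross-validation, explained-X-variance
#' latent-variable selection), refit the winning recipe, and score the
#' held-out validation partition with R2P, RMSEP, SEP, bias and slope.
#' All preprocessing statistics and model choices see calibration data
#' only.
#'
#' @param spectra a reflectance or absorbance `spectra_set`.
#' @param reference a [reference_table()] of laboratory values.
#' @param meta a [sample_meta()] with harvest-date indices.
#' @param constituents constituent columns to calibrate (default: all).
#' @param grid preprocessing recipes to search (default: the full
#'   [enumerate_grid()]).
#' @param trim wavelength window applied to every recipe (default the
#'   1350-2498 nm overlap of the two emulated instruments).
#' @param var_threshold,min_samples_per_lv latent-variable rule.
#' @param cv_splits,cv_thickness venetian-blinds parameters.
#' @param max_lv hard cap on components explored.
#' @param use_overfit_guard enable [overfit_guard()].
#' @param shared_preprocess pick one recipe for all constituents (the one
#'   minimizing mean SECV across constituents) instead of per-constituent
#'   winners.
#' @param bias_convention sign convention for validation bias.
#' @param secv_df SECV degrees of freedom (see [cross_validate()]).
#' @return An object of class `forage_calibration`; see
#'   [summary.forage_calibration()].
#' @export
forage_calibration <- function(spectra, reference, meta,
                               constituents = colnames(reference$constituents),
                               grid = enumerate_grid(),
                               trim = c(1350, 2498),
                               var_threshold = 95, min_samples_per_lv = 10,
                               cv_splits = 5, cv_thickness = 1, max_lv = 30,
                               use_overfit_guard = FALSE,
                               shared_preprocess = FALSE,
                               bias_convention = "pred_minus_lab",
                               secv_df = "n_minus_1_minus_lv") {
  al <- align_dataset(spectra, reference, meta)
  if (!is.null(trim)) grid <- lapply(grid, function(cfg) {
    cfg$trim <- trim
    cfg
  })
  split <- split_by_harvest(al$meta)
  s_cal <- al$spectra[split$calibration, ]
  s_val <- al$spectra[split$validation, ]
  ref_cal <- al$reference$constituents[split$calibration, , drop = FALSE]
  ref_val <- al$reference$constituents[split$validation, , drop = FALSE]
  searches <- lapply(stats::setNames(constituents, constituents), function(k) {
    grid_search(s_cal, ref_cal[, k], grid, cv_splits, cv_thickness,
                var_threshold, min_samples_per_lv, max_lv,
                use_overfit_guard, secv_df)
  })
  if (shared_preprocess) {
    mean_secv <- rowMeans(do.call(cbind,
                                  lapply(searches, function(g) g$table$secv)))
    shared_idx <- which.min(mean_secv)
    for (k in constituents) searches[[k]]$best_index <- shared_idx
  }
  fits <- lapply(stats::setNames(constituents, constituents), function(k) {
    gs <- searches[[k]]
    config <- grid[[gs$best_index]]
    y_cal <- ref_cal[, k]
    pp <- preprocess_train(config, s_cal)
    n <- length(y_cal)
    cap <- max(1L, min(floor(n / min_samples_per_lv), n - 1,
                       ncol(pp$spectra$signal), max_lv))
    fit <- pls_nipals(pp$spectra$signal, y_cal, ncomp = cap,
                      stop_at_cumvar = max(var_threshold, 95))
    lv <- gs$table$lv[gs$best_index]
    cv <- cross_validate(s_cal, y_cal, config, lv, cv_splits, cv_thickness,
                         secv_df)
    p_cal <- predict(fit, pp$spectra$signal, ncomp = lv)
    y_val <- ref_val[, k]
    p_val <- predict(fit, preprocess_apply(pp, s_val)$signal, ncomp = lv)
    pp$spectra <- NULL  # drop the training matrix; keep transform + center
    list(constituent = k, config = config, preprocess = pp, model = fit,
         lv = lv, grid_table = gs$table,
         calibration = eval_report("calibration", k, y_cal, p_cal, lv),
         cross_validation = eval_report("cross_validation", k, y_cal,
                                        cv$p_cv, lv),
         validation = eval_report("prediction", k, y_val, p_val, lv,
                                  bias_convention),
         p_val = p_val, y_val = y_val)
  })
  structure(list(constituents = fits,
                 calibration_ids = split$calibration,
                 validation_ids = split$validation,
                 instrument_label = al$spectra$instrument_label,
                 settings = list(trim = trim, var_threshold = var_threshold,
                                 min_samples_per_lv = min_samples_per_lv,
                                 cv_splits = cv_splits,
                                 cv_thickness = cv_thickness,
                                 max_lv = max_lv,
                                 use_overfit_guard = use_overfit_guard,
                                 shared_preprocess = shared_preprocess,
                                 bias_convention = bias_convention,
                                 secv_df = secv_df,
                                 grid_size = length(grid)),
                 call = match.call()),
            class = "forage_calibration")
}

#' @exportS3Method base::print
print.forage_calibration <- function(x, ...) {
  cat("Forage NIR calibration",
      if (nzchar(x$instrument_label)) paste0(" (", x$instrument_label, ")"),
      ": ", length(x$calibration_ids), " calibration / ",
      length(x$validation_ids), " validation samples\n", sep = "")
  s <- summary(x)
  cat("\nCalibration (SEC, SECV from venetian-blinds CV):\n")
  print(s$calibration, row.names = FALSE, digits = 3)
  cat("\nValidation (held-out odd harvest dates):\n")
  print(s$validation, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Summarize a forage calibration in the standard table schemas
#'
#' @param object a `forage_calibration`.
#' @param ... unused.
#' @return List with data frames `calibration` (constituent, recipe, LV,
#'   SEC, R2C, SECV, R2CV) and `validation` (constituent, R2P, RMSEP,
#'   SEP, bias, slope).
#' @exportS3Method base::summary
summary.forage_calibration <- function(object, ...) {
  cal <- do.call(rbind, lapply(object$constituents, function(f) {
    data.frame(constituent = f$constituent,
               preprocess = config_label(f$config), lv = f$lv,
               sec = f$calibration$sec, r2c = f$calibration$r2,
               secv = f$cross_validation$secv,
               r2cv = f$cross_validation$r2)
  }))
  val <- do.call(rbind, lapply(object$constituents, function(f) {
    data.frame(constituent = f$constituent, n = f$validation$n,
               r2p = f$validation$r2, rmsep = f$validation$rmsep,
               sep = f$validation$sep, bias = f$validation$bias,
               slope = f$validation$slope)
  }))
  rownames(cal) <- rownames(val) <- NULL
  list(calibration = cal, validation = val)
}

#' Predict constituents for new spectra from a fitted calibration
#'
#' @param object a `forage_calibration`.
#' @param newdata a `spectra_set` on the same source grid as the training
#'   spectra.
#' @param constituents which constituents to predict (default: all).
#' @param ... unused.
#' @return Numeric matrix (samples x constituents).
#' @export
predict.forage_calibration <- function(object, newdata,
                                       constituents = names(object$constituents),
                                       ...) {
  out <- vapply(constituents, function(k) {
    f <- object$constituents[[k]]
    predict(f$model, preprocess_apply(f$preprocess, newdata)$signal,
            ncomp = f$lv)
  }, numeric(length(newdata$sample_ids)))
  out <- matrix(out, nrow = length(newdata$sample_ids),
                dimnames = list(newdata$sample_ids, constituents))
  out
}

#' Validation scatter plots of a fitted calibration
#'
#' Laboratory versus predicted values on the held-out partition, with the
#' 1:1 line (dashed) and the fitted laboratory-on-predicted line (solid).
#'
#' @param x a `forage_calibration`.
#' @param constituents which constituents to plot.
#' @param ... passed to [graphics::plot()].
#' @export
plot.forage_calibration <- function(x, constituents = names(x$constituents),
                                    ...) {
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(constituents)))
  on.exit(graphics::par(old))
  for (k in constituents) {
    f <- x$constituents[[k]]
    graphics::plot(f$p_val, f$y_val, xlab = "predicted (% DM)",
                   ylab = "laboratory (% DM)", main = k, ...)
    graphics::abline(0, 1, lty = 2, col = "blue")
    graphics::abline(stats::lm(f$y_val ~ f$p_val), col = "black")
  }
  invisible(x)
}

#' Per-wavelength agreement between two instruments
#'
#' For each wavelength, the squared Pearson correlation across samples
#' between the two instruments' absorbance, plus its mean over
#' wavelengths. When the grids differ, the denser instrument is resampled
#' onto the coarser grid (restricted to the overlap): interpolating the
#' smooth dense signal introduces less artifact than upsampling the
#' coarse one. Zero-variance wavelengths are excluded and counted.
#'
#' @param a,b absorbance `spectra_set`s over the same samples.
#' @return List with `mean_r2`, `r2` (per-wavelength vector, named by
#'   wavelength), `wavelengths_nm`, `n_excluded`.
#' @export
per_wavelength_r2 <- function(a, b) {
  stopifnot(inherits(a, "spectra_set"), inherits(b, "spectra_set"))
  if (a$signal_kind != "absorbance" || b$signal_kind != "absorbance")
    stop("both spectra sets must be absorbance")
  if (!setequal(a$sample_ids, b$sample_ids))
    stop("the two spectra sets must cover the same samples")
  b <- b[a$sample_ids, ]
  if (length(a$wavelengths_nm) != length(b$wavelengths_nm) ||
      max(abs(a$wavelengths_nm - b$wavelengths_nm)) > 1e-9) {
    dense <- if (length(a$wavelengths_nm) >= length(b$wavelengths_nm)) "a" else "b"
    coarse <- if (dense == "a") b else a
    lo <- max(min(a$wavelengths_nm), min(b$wavelengths_nm))
    hi <- min(max(a$wavelengths_nm), max(b$wavelengths_nm))
    coarse <- trim_spectra(coarse, lo, hi)
    if (dense == "a") {
      a <- resample_to_grid(a, coarse$wavelengths_nm)
      b <- coarse
    } else {
      b <- resample_to_grid(b, coarse$wavelengths_nm)
      a <- coarse
    }
  }
  va <- apply(a$signal, 2, stats::var)
  vb <- apply(b$signal, 2, stats::var)
  ok <- va > 0 & vb > 0
  r2v <- rep(NA_real_, length(va))
  r2v[ok] <- vapply(which(ok), function(j) {
    stats::cor(a$signal[, j], b$signal[, j])^2
  }, numeric(1))
  names(r2v) <- format(a$wavelengths_nm, trim = TRUE)
  list(mean_r2 = mean(r2v[ok]), r2 = r2v,
       wavelengths_nm = a$wavelengths_nm, n_excluded = sum(!ok))
}

#' Compare two instruments' calibrations constituent by constituent
#'
#' Per-constituent differences (instrument B minus instrument A) in SEC,
#' R2C, SEP and R2P, and their arithmetic means across constituents.
#'
#' @param fit_a,fit_b `forage_calibration` fits over the same
#'   constituents (A is the reference instrument).
#' @return An object of class `instrument_comparison` with `deltas` (one
#'   row per constituent) and `means`.
#' @export
compare_models <- function(fit_a, fit_b) {
  sa <- summary(fit_a); sb <- summary(fit_b)
  if (!setequal(sa$calibration$constituent, sb$calibration$constituent))
    stop("the two fits cover different constituents")
  sb$calibration <- sb$calibration[match(sa$calibration$constituent,
                                         sb$calibration$constituent), ]
  sb$validation <- sb$validation[match(sa$validation$constituent,
                                       sb$validation$constituent), ]
  deltas <- data.frame(constituent = sa$calibration$constituent,
                       d_sec = sb$calibration$sec - sa$calibration$sec,
                       d_r2c = sb$calibration$r2c - sa$calibration$r2c,
                       d_sep = sb$validation$sep - sa$validation$sep,
                       d_r2p = sb$validation$r2p - sa$validation$r2p)
  means <- colMeans(deltas[, -1])
  structure(list(deltas = deltas, means = means,
                 instrument_a = fit_a$instrument_label,
                 instrument_b = fit_b$instrument_label),
            class = "instrument_comparison")
}

#' @exportS3Method base::print
print.instrument_comparison <- function(x, ...) {
  cat("Instrument comparison: ", x$instrument_b, " minus ",
      x$instrument_a, "\n", sep = "")
  print(x$deltas, row.names = FALSE, digits = 3)
  cat("\nMeans: ", paste(sprintf("%s = %+.4g", names(x$means), x$means),
                         collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Calibrate and compare both instruments of a simulated dataset
#'
#' Runs [forage_calibration()] on each instrument's spectra against the
#' laboratory-noised reference values, then compares the two with
#' [compare_models()] and [per_wavelength_r2()].
#'
#' @param dataset a `forage_sim` from [make_dataset()], or any list with
#'   `foss`, `neo`, `observed`, `meta`.
#' @param ... passed to [forage_calibration()].
#' @return List of class `instrument_study`: `foss` and `neo` fits,
#'   `comparison`, `spectral_agreement`.
#' @export
calibrate_and_validate <- function(dataset, ...) {
  fit_a <- forage_calibration(dataset$foss, dataset$observed, dataset$meta, ...)
  fit_b <- forage_calibration(dataset$neo, dataset$observed, dataset$meta, ...)
  agreement <- per_wavelength_r2(to_absorbance(dataset$foss),
                                 to_absorbance(dataset$neo))
  structure(list(foss = fit_a, neo = fit_b,
                 comparison = compare_models(fit_a, fit_b),
                 spectral_agreement = agreement),
            class = "instrument_study")
}

#' @exportS3Method base::print
print.instrument_study <- function(x, ...) {
  print(x$foss)
  cat("\n")
  print(x$neo)
  cat("\n")
  print(x$comparison)
  cat(sprintf("\nMean per-wavelength inter-instrument R2: %.3f\n",
              x$spectral_agreement$mean_r2))
  invisible(x)
}

#' Write calibration, validation and comparison reports to disk
#'
#' Writes `calibration_report.csv` and `validation_report.csv` (one row
#' per constituent and instrument), `comparison.csv`, and a
#' machine-readable `run_manifest.json` recording settings, chosen
#' recipes and latent-variable counts.
#'
#' @param study an `instrument_study`, or a single `forage_calibration`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_reports <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fits <- if (inherits(study, "forage_calibration")) list(study) else
    Filter(function(x) inherits(x, "forage_calibration"), unclass(study))
  cal <- do.call(rbind, lapply(fits, function(f) {
    cbind(instrument = f$instrument_label, summary(f)$calibration)
  }))
  val <- do.call(rbind, lapply(fits, function(f) {
    cbind(instrument = f$instrument_label, summary(f)$validation)
  }))
  utils::write.csv(cal, file.path(dir, "calibration_report.csv"),
                   row.names = FALSE)
  utils::write.csv(val, file.path(dir, "validation_report.csv"),
                   row.names = FALSE)
  if (inherits(study, "instrument_study")) {
    utils::write.csv(study$comparison$deltas, file.path(dir, "comparison.csv"),
                     row.names = FALSE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("foragenirs")),
    instruments = lapply(fits, function(f) list(
      label = f$instrument_label, settings = f$settings,
      chosen = lapply(f$constituents, function(k) list(
        preprocess = config_label(k$config), lv = k$lv)))))
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
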