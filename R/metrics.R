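#' NIRS calibration and validation error statistics
#'
#' The standard chemometric error statistics relating laboratory reference
#' values `L` to NIRS-predicted values `P`:
#'
#' \itemize{
#'   \item SEC / SECV: `sqrt(sum((L - P)^2) / (N - 1 - LV))` — standard
#'     error of calibration (or of cross-validation, applied to pooled
#'     out-of-fold predictions), with degrees of freedom charged for the
#'     `LV` latent variables.
#'   \item RMSEP: `sqrt(sum((L - P)^2) / (N - 1))` — root mean square
#'     error of prediction on an independent set.
#'   \item SEP: the bias-corrected RMSEP,
#'     `sqrt((sum((L-P)^2) - sum(L-P)^2 / N) / (N - 1))`.
#' }
#'
#' These satisfy the exact identity
#' `(N-1) * RMSEP^2 = (N-1) * SEP^2 + N * bias^2`.
#'
#' @param L numeric vector of laboratory reference values.
#' @param P numeric vector of predicted values, same length as `L`.
#' @param lv number of latent variables in the model (SEC/SECV only).
#' @name nirs_errors
NULL

check_pair <- function(L, P) {
  if (length(L) != length(P)) stop("L and P must have the same length")
  if (anyNA(L) || anyNA(P)) stop("L and P must not contain NA")
  length(L)
}

#' @rdname nirs_errors
#' @export
sec <- function(L, P, lv) {
  n <- check_pair(L, P)
  df <- n - 1 - lv
  if (df <= 0) stop("need N - 1 - LV > 0 (N = ", n, ", LV = ", lv, ")")
  sqrt(sum((L - P)^2) / df)
}

#' @rdname nirs_errors
#' @param P_cv pooled out-of-fold cross-validation predictions.
#' @export
secv <- function(L, P_cv, lv) sec(L, P_cv, lv)

#' @rdname nirs_errors
#' @param denominator `"n_minus_1"` (the conventional NIRS form used here)
#'   or `"n"`.
#' @export
rmsep <- function(L, P, denominator = c("n_minus_1", "n")) {
  denominator <- match.arg(denominator)
  n <- check_pair(L, P)
  if (n < 2) stop("need at least 2 samples")
  sqrt(sum((L - P)^2) / if (denominator == "n") n else n - 1)
}

#' @rdname nirs_errors
#' @export
sep <- function(L, P) {
  n <- check_pair(L, P)
  if (n < 2) stop("need at least 2 samples")
  r <- L - P
  rad <- (sum(r^2) - sum(r)^2 / n) / (n - 1)
  if (rad < 0) {
    if (rad < -1e-12) stop("negative radicand in SEP")
    rad <- 0
  }
  sqrt(rad)
}

#' Bias and slope of the laboratory-vs-predicted relationship
#'
#' Bias is `mean(P) - mean(L)` by default (predicted minus laboratory;
#' set `convention = "lab_minus_pred"` to flip the sign). Slope is the
#' ordinary least-squares slope of the laboratory values regressed on the
#' predictions, i.e. the slope of the line drawn through a
#' laboratory-vs-predicted validation scatter plot.
#'
#' @inheritParams nirs_errors
#' @param convention sign convention for the bias.
#' @return Named numeric vector `c(bias = ..., slope = ...)`.
#' @export
bias_slope <- function(L, P, convention = c("pred_minus_lab", "lab_minus_pred")) {
  convention <- match.arg(convention)
  n <- check_pair(L, P)
  if (n < 2) stop("need at least 2 samples")
  if (stats::var(P) == 0) stop("predictions are constant; slope undefined")
  b <- mean(P) - mean(L)
  if (convention == "lab_minus_pred") b <- -b
  slope <- stats::cov(L, P) / stats::var(P)
  c(bias = b, slope = slope)
}

#' Coefficient of determination as squared Pearson correlation
#'
#' Used for all three contexts (calibration, cross-validation, prediction),
#' so it is invariant under orientation-preserving affine maps of either
#' argument; systematic bias and slope are reported separately by
#' [bias_slope()].
#'
#' @inheritParams nirs_errors
#' @return Squared Pearson correlation in \[0, 1\].
#' @export
r2 <- function(L, P) {
  n <- check_pair(L, P)
  if (n < 2) stop("need at least 2 samples")
  if (stats::var(L) == 0 || stats::var(P) == 0)
    stop("zero variance in L or P")
  stats::cor(L, P)^2
}

#' Laboratory-error ceiling on the coefficient of determination
#'
#' The maximum R2 a calibration could attain if the spectra and model
#' introduced no error at all, given the spread of the calibration set
#' (SDL, its standard deviation) and the replicate error of the reference
#' assay (SEL): `(SDL^2 - SEL^2) / SDL^2`. When `sel >= sdl` the data
#' cannot support any calibration and the ceiling is clamped to 0, with
#' attribute `clamped = TRUE` and a warning.
#'
#' @param sdl standard deviation of the laboratory values in the
#'   calibration set (% DM).
#' @param sel standard error of the laboratory (% DM), strictly positive.
#' @param digits if non-`NULL`, round the result for reporting (the
#'   conventional presentation uses 2 decimals).
#' @return The R2 ceiling (numeric scalar).
#' @export
r2max <- function(sdl, sel, digits = NULL) {
  if (sel <= 0) stop("sel must be strictly positive")
  if (sdl <= 0) stop("sdl must be strictly positive")
  if (sel >= sdl) {
    warning("SEL >= SDL: laboratory error exceeds data spread; returning 0")
    out <- structure(0, clamped = TRUE)
  } else {
    out <- (sdl^2 - sel^2) / sdl^2
  }
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Evaluation report rows in the calibration/validation table schema
#'
#' Builds one row of the standard reporting schema: calibration context
#' rows carry n, LV, SEC and R2C; cross-validation rows SECV and R2CV;
#' prediction rows R2P, RMSEP, SEP, bias and slope.
#'
#' @param context one of `"calibration"`, `"cross_validation"`,
#'   `"prediction"`.
#' @param constituent constituent name.
#' @inheritParams nirs_errors
#' @param bias_convention passed to [bias_slope()] (prediction context).
#' @return A one-row data frame.
#' @export
eval_report <- function(context = c("calibration", "cross_validation",
                                    "prediction"),
                        constituent, L, P, lv = NA_integer_,
                        bias_convention = "pred_minus_lab") {
  context <- match.arg(context)
  n <- check_pair(L, P)
  out <- data.frame(context = context, constituent = constituent, n = n,
                    lv = lv, sec = NA_real_, secv = NA_real_,
                    rmsep = NA_real_, sep = NA_real_, bias = NA_real_,
                    slope = NA_real_, r2 = r2(L, P))
  if (context == "calibration") out$sec <- sec(L, P, lv)
  if (context == "cross_validation") out$secv <- secv(L, P, lv)
  if (context == "prediction") {
    out$rmsep <- rmsep(L, P)
    out$sep <- sep(L, P)
    bs <- bias_slope(L, P, bias_convention)
    out$bias <- bs[["bias"]]
    out$slope <- bs[["slope"]]
  }
  out
}
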