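#' Fit a univariate PLS regression by NIPALS
#'
#' Classical PLS1 with X and y deflation. For a univariate response the
#' NIPALS inner iteration has a closed-form fixed point: each component's
#' weight vector is the normalized covariance direction `X' y / ||X' y||`,
#' computed directly on the deflated matrices, so the fit is deterministic
#' and tolerance-free (`tol` and `max_iter` are retained in the signature
#' for interface compatibility; the direct computation is the converged
#' iterative solution). X and y are centered internally; the centering
#' vectors are stored so prediction is the affine map
#' `yhat = y_mean + (x - x_mean) %*% B`.
#'
#' @param X numeric matrix of predictors (samples x channels), uncentered.
#' @param y numeric response vector, length `nrow(X)`.
#' @param ncomp maximum number of latent variables to extract; at most
#'   `min(nrow(X) - 1, ncol(X))`.
#' @param tol,max_iter NIPALS iteration controls (see Details above).
#' @param stop_at_cumvar if non-`NULL`, stop extracting components once
#'   the cumulative explained X variance (percent) reaches this value --
#'   a computational shortcut for latent-variable selection.
#' @return An object of class `nipals_pls` with components `weights` (W),
#'   `x_loadings` (P), `y_loadings` (q), `scores` (T), `x_mean`, `y_mean`,
#'   `explained_x_pct`, `ssx` (total centered X sum of squares), `n_lv`,
#'   `convergence_iters`, `fitted.values`, `residuals`, `y`.
#' @seealso [predict.nipals_pls()], [select_lvs()], [explained_x_variance()]
#' @export
pls_nipals <- function(X, y, ncomp, tol = 1e-10, max_iter = 500,
                       stop_at_cumvar = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n != length(y)) stop("nrow(X) != length(y)")
  if (n < 2) stop("need at least 2 samples")
  if (stats::var(y) == 0) stop("zero-variance response")
  if (ncomp < 1 || ncomp > min(n - 1, p))
    stop("ncomp must be in [1, min(nrow - 1, ncol)] = [1, ", min(n - 1, p), "]")
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xd <- X - rep(x_mean, each = n)
  ssx <- sum(Xd^2)
  yd <- y - y_mean
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  expl <- numeric(ncomp)
  iters <- integer(ncomp)
  a <- 0
  while (a < ncomp) {
    w <- drop(crossprod(Xd, yd))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-14) break  # response variance exhausted
    w <- w / wn
    tt <- drop(Xd %*% w)
    tt2 <- sum(tt^2)
    if (tt2 < 1e-14) break
    pv <- drop(crossprod(Xd, tt)) / tt2
    qa <- sum(yd * tt) / tt2
    a <- a + 1
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- tt; q[a] <- qa
    expl[a] <- 100 * tt2 * sum(pv^2) / ssx
    iters[a] <- 1  # closed-form fixed point, one pass
    Xd <- Xd - tcrossprod(tt, pv)
    yd <- yd - qa * tt
    if (!is.null(stop_at_cumvar) && sum(expl[seq_len(a)]) >= stop_at_cumvar)
      break
  }
  if (a == 0) stop("no latent variable could be extracted")
  keep <- seq_len(a)
  fitted <- y_mean + drop(Tm[, keep, drop = FALSE] %*% q[keep])
  structure(
    list(n_lv = a,
         weights = W[, keep, drop = FALSE],
         x_loadings = P[, keep, drop = FALSE],
         y_loadings = q[keep],
         scores = Tm[, keep, drop = FALSE],
         x_mean = x_mean, y_mean = y_mean,
         explained_x_pct = expl[keep], ssx = ssx,
         convergence_iters = iters[keep],
         fitted.values = fitted, residuals = y - fitted, y = y,
         call = match.call()),
    class = "nipals_pls")
}

#' Regression coefficients of a fitted PLS model
#'
#' Collapses the Krylov factorization to the affine form
#' `yhat = intercept + x %*% B`, with
#' `B = W (P' W)^{-1} q` using the first `ncomp` components.
#'
#' @param object a `nipals_pls` fit.
#' @param ncomp number of latent variables to use (default: all fitted).
#' @param ... unused.
#' @return Numeric coefficient vector with attribute `"intercept"`.
#' @export
coef.nipals_pls <- function(object, ncomp = object$n_lv, ...) {
  k <- check_ncomp(object, ncomp)
  W <- object$weights[, 1:k, drop = FALSE]
  P <- object$x_loadings[, 1:k, drop = FALSE]
  q <- object$y_loadings[1:k]
  B <- drop(W %*% solve(crossprod(P, W), q))
  attr(B, "intercept") <- object$y_mean - sum(object$x_mean * B)
  B
}

check_ncomp <- function(object, ncomp) {
  if (ncomp < 1 || ncomp > object$n_lv)
    stop("ncomp must be in [1, ", object$n_lv, "]")
  as.integer(ncomp)
}

#' Predict from a fitted NIPALS PLS model
#'
#' @param object a `nipals_pls` fit.
#' @param newdata numeric matrix (samples x channels) on the same channel
#'   grid as the training matrix, or a `spectra_set`.
#' @param ncomp number of latent variables to use.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.nipals_pls <- function(object, newdata, ncomp = object$n_lv, ...) {
  if (inherits(newdata, "spectra_set")) newdata <- newdata$signal
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean))
    stop("newdata has ", ncol(newdata), " channels; model was trained on ",
         length(object$x_mean))
  B <- coef(object, ncomp)
  drop(attr(B, "intercept") + newdata %*% B)
}

#' @export
fitted.nipals_pls <- function(object, ...) object$fitted.values

#' @export
residuals.nipals_pls <- function(object, ...) object$residuals

#' @exportS3Method base::print
print.nipals_pls <- function(x, ...) {
  cat("NIPALS PLS1 fit: ", length(x$y), " samples, ",
      length(x$x_mean), " channels, ", x$n_lv, " latent variable",
      if (x$n_lv > 1) "s", "\n", sep = "")
  cat("Cumulative explained X variance (%):",
      paste(sprintf("%.1f", cumsum(x$explained_x_pct)), collapse = " "), "\n")
  invisible(x)
}

#' @exportS3Method base::summary
summary.nipals_pls <- function(object, ...) {
  tab <- data.frame(lv = seq_len(object$n_lv),
                    explained_x_pct = object$explained_x_pct,
                    cum_explained_x_pct = cumsum(object$explained_x_pct))
  rmse <- sqrt(mean(object$residuals^2))
  structure(list(table = tab, n = length(object$y), rmse = rmse,
                 r2 = r2(object$y, object$fitted.values)),
            class = "summary.nipals_pls")
}

#' @exportS3Method base::print
print.summary.nipals_pls <- function(x, ...) {
  cat("NIPALS PLS1, n =", x$n, "\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("Training RMSE %.4g, R2 %.4f\n", x$rmse, x$r2))
  invisible(x)
}

#' @export
plot.nipals_pls <- function(x, ...) {
  graphics::barplot(cumsum(x$explained_x_pct),
                    names.arg = seq_len(x$n_lv),
                    xlab = "latent variables",
                    ylab = "cumulative explained X variance (%)", ...)
  graphics::abline(h = 95, lty = 2)
  invisible(x)
}

#' Per-component explained X variance
#'
#' Component `a` explains `100 * ||t_a p_a'||_F^2 / ||X_centered||_F^2`
#' percent of the centered predictor sum of squares.
#'
#' @param model a `nipals_pls` fit.
#' @return Numeric vector of per-LV percentages.
#' @export
explained_x_variance <- function(model) {
  stopifnot(inherits(model, "nipals_pls"))
  model$explained_x_pct
}

#' Select the number of latent variables
#'
#' The automated rule: the smallest number of components whose cumulative
#' explained X variance reaches `var_threshold` percent, capped so that at
#' least `min_samples_per_lv` calibration samples support each component
#' (`floor(n_samples / min_samples_per_lv)`), and never below 1.
#'
#' @param cum_explained_x nondecreasing vector of cumulative explained X
#'   variance, in percent.
#' @param n_samples number of calibration samples.
#' @param var_threshold percent of X variance to explain (95 by default;
#'   99 is the aggressive variant).
#' @param min_samples_per_lv data points required per component.
#' @return Integer number of latent variables.
#' @export
select_lvs <- function(cum_explained_x, n_samples, var_threshold = 95,
                       min_samples_per_lv = 10) {
  if (length(cum_explained_x) == 0) stop("empty cumulative variance vector")
  if (any(diff(cum_explained_x) < -1e-8))
    stop("cumulative explained variance must be nondecreasing")
  hit <- which(cum_explained_x >= var_threshold)
  k <- if (length(hit)) hit[1] else length(cum_explained_x)
  cap <- max(1L, floor(n_samples / min_samples_per_lv))
  max(1L, min(as.integer(k), cap))
}

#' Guard the latent-variable count against overfitting
#'
#' Compares the cross-validation error over 1..k components: if some
#' smaller model beats the selected one by more than `rel_tol` (relative),
#' the count is reduced to that argmin; within the tolerance band the
#' original count is kept. Off by default in the pipeline.
#'
#' @param secv_by_lv SECV at 1..at least `k` components.
#' @param k the candidate count from [select_lvs()].
#' @param rel_tol relative improvement needed to override (default 1%).
#' @return Integer number of latent variables, `<= k`.
#' @export
overfit_guard <- function(secv_by_lv, k, rel_tol = 0.01) {
  if (length(secv_by_lv) < k) stop("need SECV for components 1..k")
  j <- which.min(secv_by_lv[1:k])
  if (secv_by_lv[j] < secv_by_lv[k] * (1 - rel_tol)) as.integer(j) else
    as.integer(k)
}

#' Serialize a fitted PLS model to JSON
#'
#' Full-precision JSON round trip for model reuse outside the fitting
#' session.
#'
#' @param model a `nipals_pls` fit.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pls_json <- function(model, path) {
  stopifnot(inherits(model, "nipals_pls"))
  out <- model[c("n_lv", "weights", "x_loadings", "y_loadings", "scores",
                 "x_mean", "y_mean", "explained_x_pct", "ssx",
                 "convergence_iters", "fitted.values", "residuals", "y")]
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a serialized PLS model back from JSON
#' @param path path written by [write_pls_json()].
#' @return A `nipals_pls` object.
#' @export
read_pls_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("weights", "x_loadings", "scores"))
    raw[[f]] <- as.matrix(raw[[f]])
  raw$n_lv <- as.integer(raw$n_lv)
  raw$call <- NULL
  structure(raw, class = "nipals_pls")
}
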