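test_that("NIPALS recovers an exact rank-1 relationship with one component", {
  d <- exact_rank_data()
  fit <- pls_nipals(d$X, d$y, ncomp = 1)
  expect_lt(max(abs(residuals(fit))), 1e-8)
  expect_equal(fit$explained_x_pct, 100, tolerance = 1e-9)
})

test_that("full-rank PLS reproduces OLS and scores are orthogonal", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 12; p <- 5
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    fit <- pls_nipals(X, y, ncomp = p)
    ols <- lm.fit(cbind(1, X), y)
    expect_equal(fit$fitted.values, unname(ols$fitted.values),
                 tolerance = 1e-6)
    G <- crossprod(fit$scores)
    offdiag <- abs(G[upper.tri(G)]) / sqrt(diag(G)[1] * diag(G)[2])
    expect_lt(max(offdiag), 1e-8)
  }
})

test_that("predictions match an independent reference PLS implementation", {
  requireNamespace("mixOmics", quietly = TRUE)
  for (seed in 1:5) {
    set.seed(seed)
    n <- 20; p <- 10
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
    y <- rnorm(n)
    fit <- pls_nipals(X, y, ncomp = 3)
    ref <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = FALSE)
    Xnew <- matrix(rnorm(5 * p), 5, p, dimnames = list(NULL, colnames(X)))
    refp <- predict(ref, Xnew)$predict[, 1, 3]
    expect_equal(predict(fit, Xnew, ncomp = 3), unname(refp),
                 tolerance = 1e-6)
  }
})

test_that("deflation conserves the X sum of squares", {
  set.seed(7)
  X <- matrix(rnorm(25 * 12), 25, 12)
  y <- rnorm(25)
  fit <- pls_nipals(X, y, ncomp = 6)
  Xc <- scale(X, scale = FALSE)
  Xres <- Xc - tcrossprod(fit$scores, t(t(fit$x_loadings)))
  expect_equal(fit$ssx,
               fit$ssx * sum(fit$explained_x_pct) / 100 + sum(Xres^2),
               tolerance = 1e-6)
})

test_that("explained X variance accounting is exact", {
  d <- exact_rank_data(n = 15, p = 6)
  expect_equal(explained_x_variance(pls_nipals(d$X, d$y, 1)), 100,
               tolerance = 1e-9)
  # orthonormal zero-mean columns: y aligned with one column means the
  # first component explains exactly that column's share of the SS
  n <- 20; p <- 4
  B <- cbind(stats::poly(seq_len(n), p))
  colshare <- 100 * colSums(B^2) / sum(B^2)
  fit <- pls_nipals(B, B[, 2], ncomp = 1)
  expect_equal(fit$explained_x_pct, unname(colshare[2]), tolerance = 1e-8)
  # completeness: all extractable components account for all of X
  set.seed(2)
  X <- matrix(rnorm(10 * 6), 10, 6)
  y <- rnorm(10)
  full <- pls_nipals(X, y, ncomp = 6)
  expect_equal(sum(full$explained_x_pct), 100, tolerance = 1e-6)
})

test_that("prediction is the stored affine map", {
  set.seed(4)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- rnorm(30)
  fit <- pls_nipals(X, y, ncomp = 3)
  expect_equal(predict(fit, rbind(fit$x_mean)), fit$y_mean, tolerance = 1e-10)
  expect_equal(predict(fit, X),
               fit$y_mean + drop(fit$scores %*% fit$y_loadings),
               tolerance = 1e-8)
  B <- coef(fit, 2)
  expect_equal(predict(fit, X, ncomp = 2),
               drop(attr(B, "intercept") + X %*% B))
  expect_error(predict(fit, X[, 1:5]), "channels")
  expect_error(pls_nipals(X, rep(1, 30), 2), "zero-variance")
  expect_error(pls_nipals(X, y, ncomp = 40), "ncomp")
})

test_that("latent-variable selection follows the variance-and-support rule", {
  cum <- c(60, 85, 96, 99)
  expect_equal(select_lvs(cum, 284), 3)
  expect_equal(select_lvs(cum, 25), 2)     # capped at floor(25/10)
  expect_equal(select_lvs(96, 284), 1)
  expect_equal(select_lvs(c(50, 60, 70), 284), 3)  # threshold never reached
  expect_equal(select_lvs(cum, 284, var_threshold = 99), 4)
  expect_equal(select_lvs(cum, 5), 1)      # floor never below 1
  expect_error(select_lvs(numeric(0), 284), "empty")
  expect_error(select_lvs(c(90, 80), 284), "nondecreasing")
})

test_that("the overfit guard only intervenes beyond its tolerance", {
  expect_equal(overfit_guard(c(2.0, 1.8, 1.5, 1.2), 4), 4)  # decreasing
  expect_equal(overfit_guard(c(2.0, 1.5, 1.6, 1.9), 4), 2)
  expect_equal(overfit_guard(c(1.000, 0.995, 0.999, 1.000), 4), 4)  # within 1%
  expect_error(overfit_guard(c(1, 2), 3), "1..k")
})

test_that("PLS models survive a JSON round trip at full precision", {
  set.seed(6)
  X <- matrix(rnorm(15 * 7), 15, 7)
  y <- rnorm(15)
  fit <- pls_nipals(X, y, ncomp = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_pls_json(fit, path)
  back <- read_pls_json(path)
  expect_equal(back$weights, unname(fit$weights), tolerance = 1e-12)
  Xnew <- matrix(rnorm(4 * 7), 4, 7)
  expect_equal(predict(back, Xnew), predict(fit, Xnew), tolerance = 1e-12)
})
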