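test_that("the default ridge grid is geometric from 1e-6 up to order 1e8", {
  g <- lambda_grid()
  expect_length(g, 54)
  expect_equal(g[1], 1e-6)
  expect_equal(g[54], 1e-6 * 1.848^53, tolerance = 1e-12)
  expect_gt(g[54], 1e8)
  expect_lt(g[54], 2e8)
  expect_true(all(diff(g) > 0))

  lin <- lambda_grid(progression = "linear")
  expect_equal(lin[1], 1e-6)
  expect_lt(max(lin), 1e-3)  # the linear reading cannot reach the range

  expect_error(lambda_grid(lambda0 = 0), "positive")
  expect_error(lambda_grid(ratio = 0.5), "exceed 1")
})

test_that("lag expansion produces one column per lag with exact placement", {
  x <- white_features(2, 2, 256, fs = 200, seed = 60)
  X <- build_lag_matrix(x, lag_min = -0.5, lag_max = 0.5, step = 1 / 200)
  expect_equal(ncol(X), 2 * 201)
  expect_equal(nrow(X), 2 * 256)
  expect_equal(attr(X, "n_lags"), 201)

  # single lag 0 reproduces the feature matrix
  X0 <- build_lag_matrix(x, lag_min = 0, lag_max = 0)
  expect_equal(X0[, 1], as.vector(t(x$data[, 1, ])))
  expect_equal(X0[, 2], as.vector(t(x$data[, 2, ])))

  # a delta moves to the expected row under each lag
  d <- array(0, dim = c(1, 1, 64))
  d[1, 1, 10] <- 1
  xd <- feature_tensor(d, fs = 200)
  Xd <- build_lag_matrix(xd, lag_min = -3 / 200, lag_max = 3 / 200)
  lags <- c(-3, -2, -1, 0, 1, 2, 3)
  for (li in c(2, 4, 7)) {  # lags -2, 0, +3
    col <- Xd[, li]
    expect_equal(which(col == 1), 10 + lags[li])
  }

  # no leakage across trials: shifted columns are zero-padded at trial edges
  # (negative lag pulls future samples -> zeros at trial ends; positive lag
  # pulls past samples -> zeros at trial starts)
  x2 <- white_features(2, 1, 32, fs = 200, seed = 61)
  X2 <- build_lag_matrix(x2, lag_min = -2 / 200, lag_max = 2 / 200)
  expect_equal(X2[64, 1], 0)  # last row of trial 2, lag -2
  expect_equal(X2[32, 1], 0)  # last row of trial 1, lag -2
  expect_equal(X2[33, 5], 0)  # first row of trial 2, lag +2
  expect_false(X2[34 , 4] == 0 && X2[35, 4] == 0)

  expect_error(build_lag_matrix(x, step = 1 / 300), "commensurate")
})

test_that("ridge regression matches the normal equations and its limits", {
  set.seed(62)
  X <- matrix(rnorm(500), 50, 10)
  y <- rnorm(50)
  fit <- ridge_fit(X, y, 3.7)
  Xc <- scale(X, scale = FALSE)
  ref <- solve(crossprod(Xc) + 3.7 * diag(10), crossprod(Xc, y - mean(y)))
  expect_equal(fit$beta, drop(ref), tolerance = 1e-9)

  ols <- ridge_fit(X, y, 0)
  lmref <- unname(coef(lm(y ~ X)))
  expect_equal(c(ols$intercept, ols$beta), lmref, tolerance = 1e-8)

  big <- ridge_fit(X, y, 1e12)
  expect_lt(sqrt(sum(big$beta^2)), 1e-6 * sqrt(sum(ols$beta^2)))

  # singular design with no penalty falls back to minimum norm
  Xs <- cbind(X[, 1], X[, 1], X[, 2])
  expect_warning(mn <- ridge_fit(Xs, y, 0), "minimum-norm")
  expect_equal(mn$beta[1], mn$beta[2], tolerance = 1e-8)
})

test_that("the ridge coefficient norm is non-increasing along the grid", {
  set.seed(63)
  X <- matrix(rnorm(60 * 12), 60, 12)
  y <- rnorm(60)
  norms <- vapply(lambda_grid(), function(l) {
    sqrt(sum(ridge_fit(X, y, l)$beta^2))
  }, 0)
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("a single-lambda grid reduces nested CV to plain blocked CV", {
  sim <- simulate_feature_level(n_trials = 15, n_features = 2, trial_len = 96,
                                fs = 100, snr_db = 5, seed = 64)
  lam <- 1
  got <- nested_cv_mtrf(sim$x, sim$y, grid = lambda_grid(lambda0 = lam,
                                                         n_steps = 1),
                        lag_min = -0.05, lag_max = 0.05, k_outer = 5)
  # independent plain blocked CV written out longhand
  L <- 96
  Xall <- build_lag_matrix(sim$x, lag_min = -0.05, lag_max = 0.05)
  yall <- as.vector(t(sim$y$data))
  fold <- blocked_kfold(15, 5)
  ref <- numeric(0)
  for (f in 1:5) {
    rows_of <- function(tl) as.vector(vapply(tl, function(t0) {
      ((t0 - 1) * L + 1):(t0 * L)
    }, integer(L)))
    fit <- ridge_fit(Xall[rows_of(which(fold != f)), ], yall[rows_of(which(fold != f))], lam)
    for (t0 in which(fold == f)) {
      p <- drop(Xall[rows_of(t0), ] %*% fit$beta) + fit$intercept
      ref <- c(ref, pearson_r(p, yall[rows_of(t0)]))
    }
  }
  expect_equal(got$scores$r, ref, tolerance = 1e-10)
  expect_true(all(got$scores$lambda == lam))
})

test_that("nested CV selects a near-oracle penalty on a realizable lagged system", {
  set.seed(65)
  K <- 15; L <- 96; fs <- 100
  xarr <- array(rnorm(K * 2 * L), dim = c(K, 2, L))
  w1 <- c(0.8, -0.5, 0.3); w2 <- c(-0.4, 0.6)
  y <- matrix(0, K, L)
  for (k in 1:K) {
    y[k, ] <- stats::filter(xarr[k, 1, ], w1, sides = 1)
    y[k, ] <- ifelse(is.na(y[k, ]), 0, y[k, ]) +
      c(stats::filter(xarr[k, 2, ], w2, sides = 1)[-1], 0)
  }
  y <- y + 0.3 * matrix(rnorm(K * L), K, L)
  x <- feature_tensor(xarr, fs = fs)
  yt <- target_set(y, fs = fs)
  grid <- lambda_grid(n_steps = 20, ratio = 4)
  got <- nested_cv_mtrf(x, yt, grid = grid, lag_min = -0.05, lag_max = 0.05,
                        k_outer = 5, k_inner = 4)
  expect_true(all(is.finite(got$scores$lambda)))

  # oracle: the best single lambda chosen on the test folds themselves
  oracle <- max(vapply(grid, function(l) {
    mean(nested_cv_mtrf(x, yt, grid = lambda_grid(lambda0 = l, n_steps = 1),
                        lag_min = -0.05, lag_max = 0.05,
                        k_outer = 5)$scores$r)
  }, 0))
  expect_gt(mean(got$scores$r), oracle - 0.05)
})

test_that("an uncoupled target gives chance-level mTRF decoding", {
  rs <- vapply(1:8, function(s) {
    x <- white_features(10, 2, 64, fs = 100, seed = 800 + s)
    y <- white_target(10, 64, fs = 100, seed = 900 + s)
    mean(nested_cv_mtrf(x, y, grid = lambda_grid(n_steps = 8, ratio = 100),
                        lag_min = -0.03, lag_max = 0.03, k_outer = 5,
                        k_inner = 3)$scores$r)
  }, 0)
  se <- sd(rs) / sqrt(length(rs))
  expect_lt(abs(mean(rs)), 3 * se + 0.02)
})

test_that("the coherence decoder is not worse than mTRF on its own model class", {
  sim <- simulate_feature_level(n_trials = 30, n_features = 3, trial_len = 200,
                                fs = 100, snr_db = 10, filter_len = 15,
                                seed = 11)
  r_coh <- summary(cross_validate(sim$x, sim$y, k = 5))$mean_r
  r_mtrf <- mean(nested_cv_mtrf(sim$x, sim$y, grid = lambda_grid(),
                                lag_min = -0.1, lag_max = 0.1,
                                k_outer = 5, k_inner = 4)$scores$r)
  expect_gte(r_coh, r_mtrf - 0.02)
})
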