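#' Logarithmically spaced ridge penalty grid
#'
#' Builds the geometric grid `lambda_n = lambda0 * ratio^n`,
#' `n = 0 .. n_steps - 1`. The defaults span 1e-6 up to order 1e8 in 54
#' steps with ratio 1.848. A linear progression
#' (`lambda0 * ratio * n`, with the `n = 0` term kept at `lambda0`) is
#' available for auditability but does not reach the intended range.
#'
#' @param lambda0 smallest penalty (> 0).
#' @param ratio grid ratio (> 1).
#' @param n_steps number of grid points.
#' @param progression `"geometric"` (default) or `"linear"`.
#' @return numeric vector of class `ridge_grid`, strictly increasing,
#'   starting at `lambda0`.
#' @export
lambda_grid <- function(lambda0 = 1e-6, ratio = 1.848, n_steps = 54,
                        progression = c("geometric", "linear")) {
  progression <- match.arg(progression)
  if (lambda0 <= 0) stop("lambda0 must be positive")
  if (ratio <= 1) stop("ratio must exceed 1")
  if (n_steps < 1) stop("n_steps must be at least 1")
  n <- seq_len(n_steps) - 1
  g <- if (progression == "geometric") {
    lambda0 * ratio^n
  } else {
    c(lambda0, lambda0 * ratio * n[-1L])
  }
  structure(g, class = "ridge_grid")
}

#' Lag-expanded design matrix
#'
#' Expands each feature with shifted copies of itself over the closed lag
#' range `[lag_min, lag_max]` at the given step, zero-padding at trial
#' edges so no samples leak across trials, and stacks the trials row-wise.
#' Column `(j, l)` holds `x_j(t - l)`: positive lags reach into the past,
#' negative lags into the future (the resulting temporal response function
#' is non-causal).
#'
#' @param x a [feature_tensor()].
#' @param lag_min,lag_max lag range in seconds (`lag_min <= 0 <= lag_max`).
#' @param step lag step in seconds; must be an integer number of samples.
#' @return numeric matrix `[n_trials * n_samples, n_features * n_lags]`
#'   with attributes `lags_s` (the lag values in seconds) and `n_lags`.
#' @export
build_lag_matrix <- function(x, lag_min = -0.5, lag_max = 0.5,
                             step = 1 / x$fs) {
  stopifnot(inherits(x, "feature_tensor"))
  if (lag_min > 0 || lag_max < 0) stop("lag range must contain 0")
  sstep <- step * x$fs
  if (abs(sstep - round(sstep)) > 1e-6 || round(sstep) < 1) {
    stop("lag step is not commensurate with the sampling rate")
  }
  sstep <- as.integer(round(sstep))
  lmin <- as.integer(round(lag_min * x$fs))
  lmax <- as.integer(round(lag_max * x$fs))
  lags <- seq(lmin, lmax, by = sstep)
  d <- dim(x$data)
  K <- d[1L]; FF <- d[2L]; L <- d[3L]
  if (L <= length(lags)) stop("trial length must exceed the number of lags")
  X <- matrix(0, K * L, FF * length(lags))
  for (k in seq_len(K)) {
    rows <- ((k - 1L) * L + 1L):(k * L)
    for (j in seq_len(FF)) {
      v <- x$data[k, j, ]
      for (li in seq_along(lags)) {
        l <- lags[li]
        col <- (j - 1L) * length(lags) + li
        t_idx <- seq_len(L)
        src <- t_idx - l
        ok <- src >= 1L & src <= L
        X[rows[t_idx[ok]], col] <- v[src[ok]]
      }
    }
  }
  attr(X, "lags_s") <- lags / x$fs
  attr(X, "n_lags") <- length(lags)
  X
}

#' Ridge regression fit
#'
#' Solves `(X'X + lambda I) beta = X'y` on centered data; the intercept is
#' recovered from the means and excluded from the penalty. With
#' `lambda = 0` and a singular Gram matrix, the minimum-norm solution is
#' returned with a warning.
#'
#' @param X design matrix.
#' @param y response vector, `length(y) == nrow(X)`.
#' @param lambda non-negative penalty.
#' @return list with `beta` (coefficients) and `intercept`.
#' @export
ridge_fit <- function(X, y, lambda) {
  if (nrow(X) != length(y)) stop("rows(X) must equal length(y)")
  if (lambda < 0) stop("lambda must be non-negative")
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2L, xbar)
  yc <- y - ybar
  G <- crossprod(Xc)
  if (lambda == 0) {
    qrd <- qr(Xc)
    if (qrd$rank < ncol(Xc)) {
      warning("singular design with lambda = 0; using the minimum-norm solution")
      beta <- drop(MASS::ginv(Xc) %*% yc)
    } else {
      beta <- qr.coef(qrd, yc)
    }
  } else {
    diag(G) <- diag(G) + lambda
    beta <- drop(solve(G, crossprod(Xc, yc)))
  }
  list(beta = unname(beta), intercept = ybar - sum(xbar * beta))
}

# Full solution path over a lambda grid via one SVD of the centered design.
ridge_path <- function(X, y, lambdas) {
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2L, xbar)
  yc <- y - ybar
  sv <- svd(Xc, nu = min(dim(Xc)), nv = min(dim(Xc)))
  uty <- crossprod(sv$u, yc)
  betas <- vapply(lambdas, function(l) {
    shrink <- if (l == 0) {
      ifelse(sv$d > max(sv$d) * 1e-10, 1 / sv$d, 0)
    } else {
      sv$d / (sv$d^2 + l)
    }
    drop(sv$v %*% (shrink * uty))
  }, numeric(ncol(X)))
  list(betas = matrix(betas, ncol = length(lambdas)),
       intercepts = ybar - drop(crossprod(xbar, matrix(betas, ncol = length(lambdas)))))
}

#' Nested cross-validation for the lagged ridge (mTRF) baseline
#'
#' Baseline decoder: multivariate temporal response function mapping
#' lag-expanded neural features to the target by ridge regression. The
#' penalty is chosen per outer training block by an inner blocked
#' cross-validation over the grid (maximizing the mean inner-fold per-trial
#' Pearson r), the model is refitted on the full outer training block with
#' the selected penalty, and scored on the outer test block with the same
#' fold geometry and per-trial scoring as [cross_validate()].
#'
#' @inheritParams cross_validate
#' @param grid a [lambda_grid()].
#' @param lag_min,lag_max,step lag configuration, see [build_lag_matrix()].
#' @param k_outer,k_inner outer and inner fold counts.
#' @return A `cohdecode_cv` object (method `"mtrf"`) whose `scores` data
#'   frame additionally records the selected `lambda` per fold.
#' @export
nested_cv_mtrf <- function(x, y, labels = NULL, grid = lambda_grid(),
                           lag_min = -0.5, lag_max = 0.5, step = 1 / x$fs,
                           k_outer = 5, k_inner = 4) {
  if (is.null(labels)) labels <- x$labels
  conds <- unique(labels)
  L <- dim(x$data)[3L]
  rows <- list()
  folds <- list()
  for (cc in conds) {
    idx <- which(labels == cc)
    Xall <- build_lag_matrix(subset_trials(x, idx),
                             lag_min = lag_min, lag_max = lag_max, step = step)
    yall <- as.vector(t(y$data[idx, , drop = FALSE]))
    fold <- blocked_kfold(length(idx), k_outer)
    folds[[cc]] <- fold
    trial_rows <- function(tl) as.vector(vapply(tl, function(t0) {
      ((t0 - 1L) * L + 1L):(t0 * L)
    }, integer(L)))
    for (f in seq_len(k_outer)) {
      tr <- which(fold != f)               # positions within the condition
      te <- which(fold == f)
      lam <- if (length(grid) == 1L) grid[1L] else {
        inner <- blocked_kfold(length(tr), k_inner)
        score <- matrix(NA_real_, k_inner, length(grid))
        for (g in seq_len(k_inner)) {
          itr <- tr[inner != g]
          ite <- tr[inner == g]
          path <- ridge_path(Xall[trial_rows(itr), , drop = FALSE],
                             yall[trial_rows(itr)], grid)
          for (li in seq_along(grid)) {
            rs <- vapply(ite, function(t0) {
              rws <- trial_rows(t0)
              p <- drop(Xall[rws, , drop = FALSE] %*% path$betas[, li]) +
                path$intercepts[li]
              if (stats::sd(p) == 0) 0 else stats::cor(p, yall[rws])
            }, 0)
            score[g, li] <- mean(rs)
          }
        }
        grid[which.max(colMeans(score))]
      }
      fitted <- ridge_fit(Xall[trial_rows(tr), , drop = FALSE],
                          yall[trial_rows(tr)], lam)
      for (t0 in te) {
        rws <- trial_rows(t0)
        p <- drop(Xall[rws, , drop = FALSE] %*% fitted$beta) + fitted$intercept
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cc, fold = f, trial = idx[t0],
          r = pearson_r(p, yall[rws]), ccc = ccc(p, yall[rws]),
          lambda = lam, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(scores = do.call(rbind, rows), folds = folds, k = k_outer,
                 method = "mtrf"),
            class = "cohdecode_cv")
}
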