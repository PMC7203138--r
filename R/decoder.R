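#' Fit a coherence-based spectro-spatial decoding model
#'
#' Fits the two-stage decoder for a single condition. First, a per-feature
#' spectral filter is learned from the cross-trial spectra
#' (`H_j(f) = Pxy_j(f) / Pxx_j(f)`, see [wiener_filter()]); each filter maps
#' one feature onto the target, capturing the frequency content and the
#' cross-trial consistent phase lag without any manually chosen bands or
#' lags. Second, the filtered outputs of all features, concatenated over the
#' training trials, are combined by ordinary least squares into a single
#' prediction `y(t) = sum_j b_j (x_j * h_j)(t) + n(t)`: the weights `b_j`
#' act as a spatial filter whose magnitudes index feature importance.
#'
#' @param x a [feature_tensor()] of training trials (one condition).
#' @param y the paired [target_set()] at the same rate and length.
#' @param eps_rel relative Tikhonov floor for the spectral division, see
#'   [wiener_filter()].
#' @param intercept include an intercept in the spatial regression
#'   (recommended: band envelopes have non-zero mean).
#' @param nfft transform length, defaulting to the trial length.
#' @param condition optional condition label stored in the model.
#' @return An object of class `cohdecode` with components `filterbank`
#'   (class `filter_bank`), `b`, `intercept`, `residual_var`,
#'   `contribution` (per-feature RMS contribution to the training
#'   prediction), `train_r`, plus bookkeeping fields. Supports `print()`,
#'   `summary()`, `coef()`, `predict()`, `fitted()`, `residuals()`,
#'   `plot()` and `simulate()`.
#' @examples
#' sim <- simulate_feature_level(n_trials = 12, n_features = 4,
#'                               trial_len = 128, fs = 200,
#'                               snr_db = Inf, seed = 1)
#' fit <- cohdecode(sim$x, sim$y)
#' fit$train_r
#' @export
cohdecode <- function(x, y, eps_rel = 1e-8, intercept = TRUE, nfft = NULL,
                      condition = NULL) {
  check_alignment(x, y)
  if (length(unique(x$labels)) > 1L) {
    stop("trials mix several conditions; use cohdecode_conditions()")
  }
  if (is.null(condition)) condition <- x$labels[1L]
  S <- cross_spectra(x, y, nfft = nfft)
  fb <- wiener_filter(S, eps_rel = eps_rel)
  Z <- apply_filterbank(x, fb)
  d <- dim(Z)
  X <- matrix(aperm(Z, c(3L, 1L, 2L)), nrow = d[1L] * d[3L], ncol = d[2L])
  yvec <- as.vector(t(y$data))
  Xd <- if (intercept) cbind(`(Intercept)` = 1, X) else X
  qrd <- qr(Xd)
  if (qrd$rank < ncol(Xd)) {
    warning("rank-deficient spatial design; using the minimum-norm solution")
    beta <- drop(MASS::ginv(Xd) %*% yvec)
  } else {
    beta <- qr.coef(qrd, yvec)
  }
  if (intercept) {
    b0 <- beta[1L]
    b <- beta[-1L]
  } else {
    b0 <- 0
    b <- beta
  }
  fit_vec <- drop(Xd %*% beta)
  res <- yvec - fit_vec
  dfres <- max(length(yvec) - ncol(Xd), 1L)
  contribution <- sqrt(colMeans(sweep(X, 2L, b, `*`)^2))
  names(b) <- names(contribution) <-
    paste(x$feature_ids$channel, x$feature_ids$band, sep = ":")
  structure(list(
    filterbank = fb, b = b, intercept = b0,
    residual_var = sum(res^2) / dfres,
    contribution = contribution,
    train_r = if (stats::sd(fit_vec) > 0) stats::cor(fit_vec, yvec) else NA_real_,
    fitted = matrix(fit_vec, nrow = d[1L], byrow = TRUE),
    residuals = matrix(res, nrow = d[1L], byrow = TRUE),
    feature_ids = x$feature_ids,
    condition = condition, fs = x$fs, nfft = fb$nfft,
    has_intercept = intercept, eps_rel = eps_rel,
    n_trials = d[1L], call = match.call()),
    class = "cohdecode")
}

#' @export
print.cohdecode <- function(x, ...) {
  cat(sprintf("<cohdecode> condition '%s': %d features, %d training trials @ %g Hz\n",
              x$condition, length(x$b), x$n_trials, x$fs))
  cat(sprintf("  training r = %.3f, residual variance = %.4g\n",
              x$train_r, x$residual_var))
  invisible(x)
}

#' @export
coef.cohdecode <- function(object, ...) {
  if (object$has_intercept) c(`(Intercept)` = object$intercept, object$b)
  else object$b
}

#' @export
residuals.cohdecode <- function(object, ...) object$residuals

#' @export
fitted.cohdecode <- function(object, ...) object$fitted

#' @export
summary.cohdecode <- function(object, ...) {
  w <- normalized_weights(object)
  top <- order(-object$contribution)[seq_len(min(5L, length(object$b)))]
  structure(list(model = object, normalized = w, top = top),
            class = "summary.cohdecode")
}

#' @export
print.summary.cohdecode <- function(x, ...) {
  m <- x$model
  print(m)
  cat("  leading features by contribution (RMS of b_j * (x_j * h_j)):\n")
  for (i in x$top) {
    cat(sprintf("    %-14s b = %+.4f  contribution = %.4g  |b| normalized = %.2f\n",
                names(m$b)[i], m$b[i], m$contribution[i], x$normalized[i]))
  }
  invisible(x)
}

#' Predict targets for new trials
#'
#' Applies the model's per-feature filters to new trials and combines them
#' with the fitted spatial weights. Trials must have the model's transform
#' length, rate and feature set.
#'
#' @param object a fitted [cohdecode()] model.
#' @param newdata a [feature_tensor()].
#' @param ... unused.
#' @return A [target_set()] of predictions (modality `"synthetic"`).
#' @export
predict.cohdecode <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "feature_tensor"))
  if (!identical(paste(newdata$feature_ids$channel, newdata$feature_ids$band),
                 paste(object$feature_ids$channel, object$feature_ids$band))) {
    stop("feature ids of newdata do not match the fitted model")
  }
  Z <- apply_filterbank(newdata, object$filterbank)
  d <- dim(Z)
  pred <- matrix(0, d[1L], d[3L])
  for (k in seq_len(d[1L])) {
    pred[k, ] <- drop(crossprod(matrix(Z[k, , ], nrow = d[2L]), object$b)) +
      object$intercept
  }
  target_set(pred, fs = object$fs, modality = "synthetic")
}

#' Simulate targets from a fitted decoder
#'
#' Draws targets from the model's generative reading: the deterministic
#' prediction for `newdata` plus i.i.d. Gaussian noise with the fitted
#' residual variance.
#'
#' @param object a fitted [cohdecode()] model.
#' @param nsim number of simulated replicates.
#' @param seed optional integer seed.
#' @param newdata a [feature_tensor()] whose trials drive the simulation
#'   (required: the model does not store its training features).
#' @param ... unused.
#' @return A list of `nsim` [target_set()] objects.
#' @export
simulate.cohdecode <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (missing(newdata)) stop("`newdata` is required to simulate from the model")
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object, newdata)
  sdr <- sqrt(object$residual_var)
  lapply(seq_len(nsim), function(i) {
    target_set(mu$data + matrix(stats::rnorm(length(mu$data), sd = sdr),
                                nrow = nrow(mu$data)),
               fs = mu$fs, modality = "synthetic")
  })
}

#' Plot a fitted decoder
#'
#' Left panel: magnitude responses `|H_j(f)|` of the per-feature filters.
#' Right panel: min-max normalized spatial weight magnitudes.
#'
#' @param x a fitted [cohdecode()] model.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cohdecode <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(x$filterbank$freqs, t(Mod(x$filterbank$H)), type = "l",
                    lty = 1, xlab = "frequency (Hz)", ylab = "|H(f)|",
                    main = sprintf("spectral filters ('%s')", x$condition), ...)
  graphics::barplot(normalized_weights(x), las = 2,
                    ylab = "normalized |b|", main = "spatial weights",
                    cex.names = 0.6)
  invisible(x)
}

#' Fit one decoder per condition
#'
#' Splits trials by condition label and fits an independent [cohdecode()]
#' model on each condition's trials (a model per finger, per word, ...).
#'
#' @param x a [feature_tensor()] with per-trial labels.
#' @param y the paired [target_set()].
#' @param labels per-trial condition labels; defaults to `x$labels`.
#' @param ... passed to [cohdecode()].
#' @return A named list of `cohdecode` models, class `cohdecode_set`.
#' @export
cohdecode_conditions <- function(x, y, labels = NULL, ...) {
  if (is.null(labels)) labels <- x$labels
  if (length(labels) != dim(x$data)[1L]) stop("one label per trial is required")
  conds <- unique(labels)
  few <- conds[vapply(conds, function(cc) sum(labels == cc), 0L) < 2L]
  if (length(few)) {
    stop(sprintf("condition '%s' has fewer than 2 trials", few[1L]))
  }
  models <- lapply(conds, function(cc) {
    idx <- which(labels == cc)
    cohdecode(subset_trials(x, idx), subset_trials(y, idx),
              condition = cc, ...)
  })
  names(models) <- conds
  structure(models, class = "cohdecode_set")
}

#' @export
print.cohdecode_set <- function(x, ...) {
  cat(sprintf("<cohdecode_set> %d condition models\n", length(x)))
  for (m in x) {
    cat(sprintf("  %-12s training r = %.3f (%d trials)\n",
                m$condition, m$train_r, m$n_trials))
  }
  invisible(x)
}

#' Min-max normalized spatial weight magnitudes
#'
#' Linearly rescales per-feature importances to `[0, 1]` for display on
#' electrode maps. By default the raw weight magnitudes `|b_j|` are
#' normalized; `measure = "contribution"` normalizes the per-feature RMS
#' contribution `|b_j| * RMS(x_j * h_j)` instead, which is invariant to how
#' scale is split between the spectral filter and the spatial weight. If
#' all values are equal the vector degenerates to 0.5 everywhere (documented
#' convention).
#'
#' @param model a fitted [cohdecode()] model.
#' @param measure `"b"` or `"contribution"`.
#' @return numeric vector in `[0, 1]`, named by feature.
#' @export
normalized_weights <- function(model, measure = c("b", "contribution")) {
  measure <- match.arg(measure)
  v <- abs(if (measure == "b") model$b else model$contribution)
  rng <- range(v)
  if (diff(rng) <= 0) {
    return(stats::setNames(rep(0.5, length(v)), names(v)))
  }
  (v - rng[1L]) / (rng[2L] - rng[1L])
}

# subset trials of a feature_tensor / target_set / trial_set
subset_trials <- function(x, idx) {
  if (inherits(x, "feature_tensor")) {
    feature_tensor(x$data[idx, , , drop = FALSE], fs = x$fs,
                   feature_ids = x$feature_ids, labels = x$labels[idx])
  } else if (inherits(x, "target_set")) {
    target_set(x$data[idx, , drop = FALSE], fs = x$fs, modality = x$modality)
  } else if (inherits(x, "trial_set")) {
    trial_set(x$data[idx, , , drop = FALSE], fs = x$fs,
              labels = x$labels[idx], channel_ids = x$channel_ids)
  } else {
    stop("unsupported type")
  }
}
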