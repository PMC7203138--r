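#' Cross-trial spectral estimation
#'
#' Estimates per-feature auto- and cross-power spectral densities between
#' neural features `x` and the target `y`, treating each trial as one
#' realization (one window) of the same random process: a Hamming taper of
#' the full trial length is applied to every trial, a DFT is taken, and the
#' periodogram cross-products are averaged across trials. This trial-as-window
#' estimator relaxes the within-trial stationarity assumption of the usual
#' segment-averaging approach; the frequency resolution is `fs / n_samples`.
#'
#' Spectra are one-sided densities (per Hz, window-power normalized), so
#' `Pxx`/`Pyy` integrate to signal power; the normalization constants cancel
#' in the coherence and in the decoding filter.
#'
#' @param x a [feature_tensor()].
#' @param y a paired [target_set()] with the same trial count, length and rate.
#' @param nfft transform length; defaults to the trial length.
#' @param window taper applied to each trial: `"hamming"` (default) or
#'   `"boxcar"` (rectangular; useful for exact recovery of circular
#'   systems).
#' @param detrend `"constant"` removes each trial's mean before tapering
#'   (standard practice, suppresses spurious near-DC coupling from
#'   trial-varying offsets); `"none"` uses the raw trials.
#' @param force set `TRUE` to pool trials whose labels mix several
#'   conditions. By default mixed-condition pooling is refused, because
#'   trials are only exchangeable realizations within one condition.
#' @return An object of class `spectra_set` with fields `freqs`, `Pxx`
#'   (`n_features x n_freq`), `Pyy`, `Pxy` (complex), `n_trials_used`,
#'   `window`, `fs`, `nfft`.
#' @export
cross_spectra <- function(x, y, nfft = NULL,
                          window = c("hamming", "boxcar"),
                          detrend = c("constant", "none"), force = FALSE) {
  window <- match.arg(window)
  detrend <- match.arg(detrend)
  check_alignment(x, y)
  K <- dim(x$data)[1L]
  if (K < 2L) stop("coherence undefined from one realization: need >= 2 trials")
  if (!force && length(unique(x$labels)) > 1L) {
    stop("trials mix several conditions; fit one model per condition, or use force = TRUE")
  }
  L <- dim(x$data)[3L]
  if (is.null(nfft)) nfft <- L
  if (nfft < L) stop("nfft must be at least the trial length")
  FF <- dim(x$data)[2L]
  w <- if (window == "hamming") hamming_periodic(L) else rep(1, L)
  u <- x$fs * sum(w^2)   # density normalization
  half <- floor(nfft / 2L) + 1L

  # tapered DFTs: Y [half x K], X [half x K x F]
  Yf <- tapered_dft(t(y$data), w, nfft, half, detrend)
  Xf <- array(0i, dim = c(half, K, FF))
  for (j in seq_len(FF)) {
    Xf[, , j] <- tapered_dft(t(matrix(x$data[, j, ], nrow = K)), w, nfft,
                             half, detrend)
  }

  sided <- one_sided_scale(nfft) / u
  Pyy <- rowMeans(Mod(Yf)^2) * sided
  Pxx <- matrix(0, FF, half)
  Pxy <- matrix(0i, FF, half)
  for (j in seq_len(FF)) {
    Pxx[j, ] <- rowMeans(Mod(Xf[, , j])^2) * sided
    Pxy[j, ] <- rowMeans(Conj(Xf[, , j]) * Yf) * sided
  }
  structure(list(freqs = (seq_len(half) - 1L) * x$fs / nfft,
                 Pxx = Pxx, Pyy = Pyy, Pxy = Pxy,
                 n_trials_used = K, window = window,
                 fs = x$fs, nfft = as.integer(nfft)),
            class = "spectra_set")
}

# columns = trials; optional constant detrend, taper, zero-pad, one-sided DFT
tapered_dft <- function(m, w, nfft, half, detrend) {
  if (detrend == "constant") m <- sweep(m, 2L, colMeans(m))
  m <- m * w
  if (nfft > nrow(m)) m <- rbind(m, matrix(0, nfft - nrow(m), ncol(m)))
  stats::mvfft(m)[seq_len(half), , drop = FALSE]
}

# Periodic Hamming taper (exactly one period of the raised cosine), so the
# circular autocorrelation of the window used in bias analysis is exact.
hamming_periodic <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1L) / n)
}

# one-sided doubling: every bin except DC (and Nyquist when nfft is even)
one_sided_scale <- function(nfft) {
  half <- floor(nfft / 2L) + 1L
  s <- rep(2, half)
  s[1L] <- 1
  if (nfft %% 2L == 0L) s[half] <- 1
  s
}

check_alignment <- function(x, y) {
  stopifnot(inherits(x, "feature_tensor"), inherits(y, "target_set"))
  if (dim(x$data)[1L] != nrow(y$data)) {
    stop("x and y disagree on the number of trials")
  }
  if (dim(x$data)[3L] != ncol(y$data)) {
    stop("x and y disagree on the trial length")
  }
  if (abs(x$fs - y$fs) > 1e-9) stop("x and y disagree on the sampling rate")
  invisible(TRUE)
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d features, %d frequency bins (0-%g Hz, df = %g Hz), %d trials\n",
              nrow(x$Pxx), length(x$freqs), max(x$freqs),
              x$freqs[2L] - x$freqs[1L], x$n_trials_used))
  invisible(x)
}

#' Complex coherence
#'
#' Normalizes the cross-spectrum by the two auto-spectra:
#' `C[j, f] = Pxy[j, f] / sqrt(Pxx[j, f] * Pyy[f])`. The squared magnitude
#' lies in `[0, 1]` and acts as a squared correlation between the feature
#' and the target at each frequency; the phase carries the cross-trial
#' consistent phase difference. Bins with zero power in either signal are
#' set to 0 and flagged.
#'
#' @param S a [cross_spectra()] result.
#' @return An object of class `coherence_spectrum` with fields `freqs` and
#'   complex matrix `C` (`n_features x n_freq`); attribute `"flagged"` marks
#'   zero-power bins.
#' @export
coherence <- function(S) {
  stopifnot(inherits(S, "spectra_set"))
  den <- sweep(S$Pxx, 2L, S$Pyy, `*`)
  flagged <- den <= 0
  den[flagged] <- 1
  C <- S$Pxy / sqrt(den)
  C[flagged] <- 0i
  structure(list(freqs = S$freqs, C = C),
            class = "coherence_spectrum", flagged = flagged)
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  pk <- apply(Mod(x$C)^2, 1L, which.max)
  cat(sprintf("<coherence_spectrum> %d features; peak |C|^2 %.3f at %g Hz\n",
              nrow(x$C), max(Mod(x$C)^2), x$freqs[pk[which.max(apply(Mod(x$C)^2, 1, max))]]))
  invisible(x)
}

#' Per-feature Wiener deconvolution filters
#'
#' Builds, for every feature, the least-squares-optimal linear filter
#' mapping the feature onto the target: `H[j, f] = Pxy[j, f] / Pxx[j, f]`.
#' The phase of `H` encodes the cross-trial consistent phase lag between
#' target and feature at each frequency, so no lag structure has to be
#' specified by hand. A relative Tikhonov floor `eps_rel * max_f Pxx[j, ]`
#' stabilizes bins where the feature has essentially no power (e.g. filter
#' stop-bands after preprocessing).
#'
#' @param S a [cross_spectra()] result.
#' @param eps_rel non-negative relative regularization floor.
#' @return An object of class `filter_bank`: one-sided `H`
#'   (`n_features x n_freq`), full Hermitian spectrum `H_full`
#'   (`n_features x nfft`), real impulse responses `h`
#'   (`n_features x nfft`), `freqs`, `fs`, `nfft`.
#' @export
wiener_filter <- function(S, eps_rel = 1e-8) {
  stopifnot(inherits(S, "spectra_set"), eps_rel >= 0)
  FF <- nrow(S$Pxx)
  floorv <- eps_rel * apply(S$Pxx, 1L, max)
  den <- S$Pxx + floorv
  zero <- den <= 0
  den[zero] <- 1
  H <- S$Pxy / den
  H[zero] <- 0i
  H_full <- hermitian_extend(H, S$nfft)
  h <- matrix(0, FF, S$nfft)
  for (j in seq_len(FF)) {
    hc <- stats::fft(H_full[j, ], inverse = TRUE) / S$nfft
    rel <- max(Mod(Im(hc))) / max(max(Mod(hc)), .Machine$double.eps)
    if (rel > 1e-6) {
      warning(sprintf("impulse response %d has imaginary residue %.2e", j, rel))
    }
    h[j, ] <- Re(hc)
  }
  structure(list(freqs = S$freqs, H = H, H_full = H_full, h = h,
                 fs = S$fs, nfft = S$nfft),
            class = "filter_bank")
}

# Extend a one-sided spectrum [F x half] to the full Hermitian DFT grid so
# the inverse transform is real; DC (and Nyquist for even nfft) are forced
# real.
hermitian_extend <- function(H, nfft) {
  if (is.null(dim(H))) H <- matrix(H, nrow = 1L)
  half <- floor(nfft / 2L) + 1L
  stopifnot(ncol(H) == half)
  full <- matrix(0i, nrow(H), nfft)
  full[, 1L] <- Re(H[, 1L])
  if (nfft %% 2L == 0L) {
    full[, half] <- Re(H[, half])
    idx <- 2L:(half - 1L)
  } else {
    idx <- 2L:half
  }
  full[, idx] <- H[, idx]
  full[, nfft + 2L - idx] <- Conj(H[, idx])
  full
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank> %d features, nfft = %d @ %g Hz\n",
              nrow(x$H), x$nfft, x$fs))
  invisible(x)
}

#' Apply a filter bank to features
#'
#' Filters every feature of every trial with its filter by frequency-domain
#' multiplication (circular convolution with the impulse response `h`). No
#' taper is applied at prediction time; the taper enters only the spectral
#' estimation.
#'
#' @param x a [feature_tensor()] whose trial length equals the filter bank's
#'   transform length.
#' @param fb a [wiener_filter()] result.
#' @return numeric array `[n_trials, n_features, nfft]` of filtered outputs.
#' @export
apply_filterbank <- function(x, fb) {
  stopifnot(inherits(x, "feature_tensor"), inherits(fb, "filter_bank"))
  d <- dim(x$data)
  if (d[3L] != fb$nfft) {
    stop(sprintf("trial length %d does not match filter transform length %d",
                 d[3L], fb$nfft))
  }
  if (abs(x$fs - fb$fs) > 1e-9) stop("sampling rate mismatch between features and filters")
  if (d[2L] != nrow(fb$H)) {
    stop(sprintf("feature count %d does not match filter bank (%d)", d[2L], nrow(fb$H)))
  }
  out <- array(0, dim = d)
  Ht <- t(fb$H_full)  # [nfft x F]
  for (k in seq_len(d[1L])) {
    Xf <- stats::mvfft(t(matrix(x$data[k, , ], nrow = d[2L])))
    out[k, , ] <- t(Re(stats::mvfft(Xf * Ht, inverse = TRUE)) / d[3L])
  }
  out
}

#' Random-phase significance threshold for coherence
#'
#' Builds an empirical null distribution for the squared coherence magnitude
#' by replacing the target's per-trial Fourier phases with i.i.d. uniform
#' phases (amplitude spectra preserved, Hermitian symmetry enforced, so each
#' surrogate target is real with the same per-trial power spectrum) and
#' recomputing the coherence for each surrogate. The threshold at each
#' `(feature, frequency)` bin is the empirical `1 - alpha` quantile over
#' surrogates; observed bins whose `|C|^2` exceeds it are deemed
#' significant.
#'
#' @param x a [feature_tensor()].
#' @param y a paired [target_set()].
#' @param alpha significance level in (0, 1).
#' @param n_surrogates number of phase-randomized surrogates (at least
#'   `1 / alpha`).
#' @param seed integer seed for the surrogate phases.
#' @param nfft transform length, defaulting to the trial length.
#' @param force see [cross_spectra()].
#' @return numeric matrix `[n_features x n_freq]` of `|C|^2` thresholds,
#'   with attribute `"freqs"`.
#' @seealso [coherence_significance()] for thresholds together with the
#'   observed coherence and the significance mask.
#' @export
random_phase_threshold <- function(x, y, alpha = 0.05, n_surrogates = 1000,
                                   seed = 1, nfft = NULL,
                                   window = c("hamming", "boxcar"),
                                   detrend = c("constant", "none"),
                                   force = FALSE) {
  window <- match.arg(window)
  detrend <- match.arg(detrend)
  check_alignment(x, y)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_surrogates < 1 / alpha) stop("n_surrogates must be at least 1/alpha")
  if (max(abs(y$data)) == 0) stop("degenerate all-zero target")
  K <- dim(x$data)[1L]
  if (K < 2L) stop("coherence undefined from one realization: need >= 2 trials")
  if (!force && length(unique(x$labels)) > 1L) {
    stop("trials mix several conditions; test one condition, or use force = TRUE")
  }
  L <- dim(x$data)[3L]
  if (is.null(nfft)) nfft <- L
  FF <- dim(x$data)[2L]
  w <- if (window == "hamming") hamming_periodic(L) else rep(1, L)
  half <- floor(nfft / 2L) + 1L

  Yf <- tapered_dft(t(y$data), w, nfft, half, detrend)
  Xf <- array(0i, dim = c(half, K, FF))
  for (j in seq_len(FF)) {
    Xf[, , j] <- tapered_dft(t(matrix(x$data[, j, ], nrow = K)), w, nfft,
                             half, detrend)
  }
  Pyy <- rowMeans(Mod(Yf)^2)
  Pxx <- matrix(0, FF, half)
  for (j in seq_len(FF)) Pxx[j, ] <- rowMeans(Mod(Xf[, , j])^2)
  den <- sweep(Pxx, 2L, Pyy, `*`)
  zero <- den <= 0
  den[zero] <- 1
  Ymag <- Mod(Yf)
  real_bins <- c(TRUE, rep(FALSE, half - 1L))
  if (nfft %% 2L == 0L) real_bins[half] <- TRUE

  set.seed(seed)
  null_c2 <- array(0, dim = c(n_surrogates, FF, half))
  for (s in seq_len(n_surrogates)) {
    ph <- matrix(stats::runif(half * K, 0, 2 * pi), half, K)
    Ys <- Ymag * exp(1i * ph)
    # DC / Nyquist must stay real: random sign, magnitude preserved
    nreal <- sum(real_bins)
    Ys[real_bins, ] <- Ymag[real_bins, , drop = FALSE] *
      matrix(sample(c(-1, 1), nreal * K, replace = TRUE), nreal, K)
    for (j in seq_len(FF)) {
      Pxy_s <- rowMeans(Conj(Xf[, , j]) * Ys)
      null_c2[s, j, ] <- Mod(Pxy_s)^2 / den[j, ]
    }
  }
  null_c2[, , ] <- pmin(null_c2, 1)
  ko <- min(n_surrogates, ceiling((n_surrogates + 1) * (1 - alpha)))
  thr <- apply(null_c2, c(2L, 3L), function(v) sort(v)[ko])
  thr[zero] <- 0
  attr(thr, "freqs") <- (seq_len(half) - 1L) * x$fs / nfft
  thr
}

#' Observed coherence with surrogate significance mask
#'
#' Convenience wrapper combining [cross_spectra()], [coherence()] and
#' [random_phase_threshold()] on the same trials.
#'
#' @inheritParams random_phase_threshold
#' @return A data frame with one row per `(feature, frequency)` bin and
#'   columns `feature_id`, `freq_hz`, `coh2`, `threshold`, `significant`.
#' @export
coherence_significance <- function(x, y, alpha = 0.05, n_surrogates = 1000,
                                   seed = 1, nfft = NULL, force = FALSE) {
  S <- cross_spectra(x, y, nfft = nfft, force = force)
  C2 <- Mod(coherence(S)$C)^2
  thr <- random_phase_threshold(x, y, alpha = alpha,
                                n_surrogates = n_surrogates, seed = seed,
                                nfft = nfft, force = force)
  fid <- paste(x$feature_ids$channel, x$feature_ids$band, sep = ":")
  data.frame(
    feature_id = rep(fid, times = ncol(C2)),
    freq_hz = rep(S$freqs, each = nrow(C2)),
    coh2 = as.vector(C2),
    threshold = as.vector(thr),
    significant = as.vector(C2 > thr),
    stringsAsFactors = FALSE)
}
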