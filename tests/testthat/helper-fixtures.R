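# shared fixture builders and small numeric helpers

white_features <- function(n_trials, n_features, n_samples, fs = 200, seed = NULL,
                           labels = NULL) {
  if (!is.null(seed)) set.seed(seed)
  feature_tensor(array(stats::rnorm(n_trials * n_features * n_samples),
                       dim = c(n_trials, n_features, n_samples)),
                 fs = fs, labels = labels)
}

white_target <- function(n_trials, n_samples, fs = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  target_set(matrix(stats::rnorm(n_trials * n_samples), n_trials, n_samples),
             fs = fs)
}

cosine_sim <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))

# amplitude of the f_hz component of x, by projection onto the quadrature
# pair over a central window (robust to slow drift, unlike max|x|)
tone_amplitude <- function(x, fs, f_hz, idx = seq_along(x)) {
  t <- (idx - 1) / fs
  c1 <- 2 * mean(x[idx] * cos(2 * pi * f_hz * t))
  c2 <- 2 * mean(x[idx] * sin(2 * pi * f_hz * t))
  sqrt(c1^2 + c2^2)
}

# magnitude response at f_hz of a zero-phase (forward-backward) filter
# cascade given as a list of Arma sections
cascade_gain <- function(sections, f_hz, fs) {
  z <- exp(-1i * 2 * pi * f_hz / fs)
  g <- 1
  for (s in sections) {
    g <- g * Mod(sum(s$b * z^(0:(length(s$b) - 1))) /
                   sum(s$a * z^(0:(length(s$a) - 1))))^2
  }
  g
}

# brute-force one-sided cross-trial spectra by explicit DFT sums; mirrors
# the estimator's contract but shares no code with it
manual_cross_spectra <- function(xarr, ymat, fs, window = "hamming",
                                 detrend = "constant") {
  K <- dim(xarr)[1L]; L <- dim(xarr)[3L]
  w <- if (window == "hamming") {
    0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / L)
  } else rep(1, L)
  half <- floor(L / 2) + 1L
  dft <- function(v, f) sum(v * exp(-2i * pi * f * (0:(L - 1)) / L))
  u <- fs * sum(w^2)
  sided <- c(1, rep(2, half - 2L), if (L %% 2 == 0) 1 else 2)[seq_len(half)]
  Pxx <- Pyy <- numeric(half)
  Pxy <- complex(half)
  for (f in seq_len(half) - 1L) {
    sxx <- syy <- 0
    sxy <- 0i
    for (k in seq_len(K)) {
      xv <- xarr[k, 1, ]; yv <- ymat[k, ]
      if (detrend == "constant") { xv <- xv - mean(xv); yv <- yv - mean(yv) }
      X <- dft(xv * w, f); Y <- dft(yv * w, f)
      sxx <- sxx + Mod(X)^2; syy <- syy + Mod(Y)^2
      sxy <- sxy + Conj(X) * Y
    }
    Pxx[f + 1L] <- sxx / K / u * sided[f + 1L]
    Pyy[f + 1L] <- syy / K / u * sided[f + 1L]
    Pxy[f + 1L] <- sxy / K / u * sided[f + 1L]
  }
  list(freqs = (seq_len(half) - 1L) * fs / L, Pxx = Pxx, Pyy = Pyy, Pxy = Pxy)
}

# direct O(n^2) circular convolution
circ_conv_direct <- function(h, x) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n)) {
    idx <- ((t - seq_len(n)) %% n) + 1L
    out[t] <- sum(h * x[idx])
  }
  out
}

# write an arbitrary PCM16 WAV (any channel count) for reader error tests
write_wav_raw <- function(samples_by_channel, fs, path) {
  nch <- nrow(samples_by_channel)
  q <- as.integer(round(pmax(-1, pmin(1, as.vector(samples_by_channel))) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- 2L * length(q)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + nbytes, con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")
  writeBin(nch, con, size = 2L, endian = "little")
  writeBin(as.integer(fs), con, size = 4L, endian = "little")
  writeBin(as.integer(fs) * 2L * nch, con, size = 4L, endian = "little")
  writeBin(2L * nch, con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(nbytes, con, size = 4L, endian = "little")
  writeBin(q, con, size = 2L, endian = "little")
  invisible(path)
}
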