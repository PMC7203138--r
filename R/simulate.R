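#' Circular convolution
#'
#' Frequency-domain circular convolution of a kernel with a signal, matching
#' the DFT framing of the spectral estimator and filter application.
#'
#' @param g kernel (length at most `length(x)`).
#' @param x signal.
#' @return numeric vector of `length(x)`.
#' @export
circ_conv <- function(g, x) {
  n <- length(x)
  if (length(g) > n) stop("kernel longer than signal")
  gp <- c(g, numeric(n - length(g)))
  Re(stats::fft(stats::fft(gp) * stats::fft(x), inverse = TRUE)) / n
}

# random smooth unit-norm FIR kernel: white taps smoothed with a raised
# cosine and tapered so energy is concentrated early in the kernel
smooth_fir <- function(len, smooth = max(3L, len %/% 5L)) {
  w <- stats::rnorm(len + 2L * smooth)
  k <- 0.5 * (1 - cos(2 * pi * seq_len(2 * smooth + 1L) / (2 * smooth + 2L)))
  g <- stats::convolve(w, k, type = "filter")[seq_len(len)]
  g <- g * 0.5 * (1 - cos(2 * pi * seq_len(len) / (len + 1L)))
  g / sqrt(sum(g^2))
}

# 1/f ("pink") noise with unit variance, generated in the frequency domain
pink_noise <- function(n) {
  half <- floor(n / 2L) + 1L
  mag <- c(0, 1 / sqrt(seq_len(half - 1L)))
  ph <- stats::runif(half, 0, 2 * pi)
  spec <- mag * exp(1i * ph)
  spec[1L] <- 0
  if (n %% 2L == 0L) spec[half] <- Mod(spec[half])
  idx <- if (n %% 2L == 0L) seq(half - 1L, 2L) else seq(half, 2L)
  full <- c(spec, Conj(spec[idx]))
  x <- Re(stats::fft(full, inverse = TRUE))
  x / stats::sd(x)
}

# band power of a vector via the DFT, used to calibrate in-band SNR
band_power <- function(x, fs, band) {
  n <- length(x)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)
  p <- Mod(stats::fft(x))^2 / n
  sum(p[f >= band[1L] & f <= band[2L]])
}

#' Simulate feature-level data from the decoder's generative model
#'
#' Draws white-noise features per trial and builds the target by the
#' model's own generative reading: `y = sum_j b_j (g_j * x_j) + noise`,
#' with random smooth unit-norm FIR kernels `g_j`, random weights `b_j`,
#' circular convolution, and white Gaussian noise scaled so the realized
#' signal-to-noise ratio equals `snr_db` exactly (use `snr_db = Inf` for a
#' noiseless, perfectly realizable system).
#'
#' @param n_trials,n_features,trial_len problem dimensions.
#' @param fs analysis sampling rate in Hz.
#' @param snr_db requested signal-to-noise ratio in dB (variance ratio of
#'   the realizable component to the added noise).
#' @param filter_len kernel length in samples.
#' @param seed integer seed; identical seeds give bit-identical outputs.
#' @return list with `x` ([feature_tensor()]), `y` ([target_set()]) and
#'   `truth`: `true_h` (kernels, `n_features x filter_len`), `true_b`,
#'   `true_contribution` (per-feature RMS of its share of the clean
#'   target), `snr_db`, `realized_snr_db`, `seed`, `fs`.
#' @export
simulate_feature_level <- function(n_trials = 30, n_features = 8,
                                   trial_len = 400, fs = 200, snr_db = 10,
                                   filter_len = 25, seed = 1) {
  if (trial_len <= filter_len) stop("trial_len must exceed filter_len")
  if (n_trials < 2L || n_features < 1L) stop("invalid problem size")
  if (!is.finite(snr_db) && snr_db < 0) stop("snr_db must be finite or +Inf")
  set.seed(seed)
  g <- t(vapply(seq_len(n_features), function(j) smooth_fir(filter_len),
                numeric(filter_len)))
  b <- stats::runif(n_features, 0.5, 1.5) *
    sample(c(-1, 1), n_features, replace = TRUE)
  x <- array(stats::rnorm(n_trials * n_features * trial_len),
             dim = c(n_trials, n_features, trial_len))
  clean <- matrix(0, n_trials, trial_len)
  css <- numeric(n_features)
  for (k in seq_len(n_trials)) {
    for (j in seq_len(n_features)) {
      cj <- b[j] * circ_conv(g[j, ], x[k, j, ])
      clean[k, ] <- clean[k, ] + cj
      css[j] <- css[j] + sum(cj^2)
    }
  }
  if (is.finite(snr_db)) {
    noise <- matrix(stats::rnorm(n_trials * trial_len), n_trials, trial_len)
    scale <- sqrt(stats::var(as.vector(clean)) /
                    (stats::var(as.vector(noise)) * 10^(snr_db / 10)))
    y <- clean + noise * scale
  } else {
    y <- clean
  }
  list(
    x = feature_tensor(x, fs = fs),
    y = target_set(y, fs = fs, modality = "synthetic"),
    truth = list(true_h = g, true_b = b,
                 true_contribution = sqrt(css / (n_trials * trial_len)),
                 snr_db = snr_db, realized_snr_db = snr_db,
                 flexion_rate_hz = NA_real_, seed = seed, fs = fs))
}

# quasi-periodic flexion trace: raised-cosine flexion cycles whose periods
# jitter i.i.d. with the given coefficient of variation
flexion_trace <- function(n, fs, rate_hz, cv = 0.1) {
  samples <- numeric(0)
  while (length(samples) < n + round(2 * fs / rate_hz)) {
    period <- max(0.2 / rate_hz, (1 / rate_hz) * (1 + cv * stats::rnorm(1)))
    d <- max(4L, round(fs * period))
    samples <- c(samples, 0.5 * (1 - cos(2 * pi * (seq_len(d) - 1L) / d)))
  }
  start <- sample.int(round(fs / rate_hz), 1L)
  samples[start:(start + n - 1L)]
}

#' Simulate raw multichannel recordings coupled to a flexion-like target
#'
#' Emulates the structure of a repetitive finger-flexion experiment: the
#' target is a quasi-periodic flexion trace (smoothed pulse train at
#' `flexion_rate_hz` with 10% period jitter), and each coupled channel
#' contains (a) an additive low-frequency component, the target convolved
#' with a smooth channel-specific kernel, and (b) a high-frequency-band
#' carrier (70-170 Hz noise) amplitude-modulated by the target, both on top
#' of pink (1/f) background noise. Uncoupled channels are pink noise only.
#' Coupling gains are calibrated so the in-band variance ratio of the
#' coupled component to the background equals `snr_db` in both the
#' low-frequency (0.5-40 Hz) and high-frequency (70-170 Hz) bands.
#'
#' @param n_trials,n_channels,trial_len problem dimensions (raw rate).
#' @param fs recording sampling rate in Hz.
#' @param snr_db in-band coupling SNR in dB.
#' @param flexion_rate_hz mean flexion rate in Hz (must be below 40).
#' @param n_coupled number of channels coupled to the target.
#' @param am_depth modulation depth of the high-gamma carrier.
#' @param seed integer seed.
#' @return list with `trials` ([trial_set()]), `y` ([target_set()]) and
#'   `truth` including the coupling gains `true_b` (0 for uncoupled
#'   channels), the kernels, and `clean_lfc`, the noise-free low-frequency
#'   coupled component per trial/channel (same shape as the data) for
#'   computing ground-truth contributions after any re-referencing.
#' @export
simulate_raw_level <- function(n_trials = 30, n_channels = 8,
                               trial_len = 2000, fs = 1000, snr_db = 10,
                               flexion_rate_hz = 2,
                               n_coupled = max(1L, round(0.75 * n_channels)),
                               am_depth = 0.8, seed = 1) {
  if (flexion_rate_hz >= 40 || flexion_rate_hz <= 0) {
    stop("flexion_rate_hz must lie in (0, 40) Hz")
  }
  if (n_coupled > n_channels) stop("n_coupled exceeds n_channels")
  set.seed(seed)
  lfc_band <- c(0.5, 40)
  hfb_band <- c(70, 170)
  klen <- max(25L, round(0.125 * fs))
  g <- t(vapply(seq_len(n_channels), function(j) smooth_fir(klen),
                numeric(klen)))
  alpha <- c(stats::runif(n_coupled, 0.85, 1.15), rep(0, n_channels - n_coupled))
  snr_lin <- 10^(snr_db / 10)

  y <- t(vapply(seq_len(n_trials),
                function(k) flexion_trace(trial_len, fs, flexion_rate_hz),
                numeric(trial_len)))
  data <- array(0, dim = c(n_trials, n_channels, trial_len))
  clean_lfc <- array(0, dim = c(n_trials, n_channels, trial_len))
  for (k in seq_len(n_trials)) {
    ymod <- y[k, ] / max(y[k, ])              # in [0, 1]
    for (j in seq_len(n_channels)) {
      bg <- pink_noise(trial_len)
      ch <- bg
      if (alpha[j] > 0) {
        comp <- circ_conv(g[j, ], y[k, ] - mean(y[k, ]))
        # calibrate the additive coupling to the requested in-band SNR
        p_sig <- band_power(comp, fs, lfc_band)
        p_bg <- band_power(bg, fs, lfc_band)
        comp <- comp * alpha[j] * sqrt(snr_lin * p_bg / p_sig)
        # high-gamma carrier, amplitude-modulated by the flexion trace
        carrier <- stats::rnorm(trial_len)
        Cf <- stats::fft(carrier)
        f <- (seq_len(trial_len) - 1L) * fs / trial_len
        f <- pmin(f, fs - f)
        Cf[f < hfb_band[1L] | f > hfb_band[2L]] <- 0i
        carrier <- Re(stats::fft(Cf, inverse = TRUE)) / trial_len
        carrier <- carrier / stats::sd(carrier)
        am <- carrier * (1 + am_depth * ymod)
        p_am <- band_power(am, fs, hfb_band)
        p_bg_h <- band_power(bg, fs, hfb_band)
        am <- am * alpha[j] * sqrt(snr_lin * p_bg_h / p_am)
        clean_lfc[k, j, ] <- comp
        ch <- ch + comp + am
      }
      data[k, j, ] <- ch
    }
  }
  list(
    trials = trial_set(data, fs = fs),
    y = target_set(y, fs = fs, modality = "glove"),
    truth = list(true_h = g, true_b = alpha, snr_db = snr_db,
                 flexion_rate_hz = flexion_rate_hz, n_coupled = n_coupled,
                 clean_lfc = clean_lfc, seed = seed, fs = fs))
}

#' Simulate a labeled multi-condition dataset with planted spatial structure
#'
#' Generates one feature-level dataset per condition from shared kernels but
#' condition-specific weights: on the designated discriminative features the
#' weight centers are spread `separation` apart across conditions (plus a
#' small common jitter), while the remaining features share one weight
#' across conditions. With `separation = 0` the conditions are statistically
#' identical and any downstream discriminability analysis should perform at
#' chance.
#'
#' @param n_conditions number of conditions (>= 2).
#' @param separation spacing between adjacent condition weight centers on
#'   the discriminative features (same units as the weights, whose common
#'   base is around 1).
#' @param n_discriminative how many features carry condition-specific
#'   weights.
#' @param n_trials_per_condition,n_features,trial_len,fs,snr_db,filter_len
#'   as in [simulate_feature_level()].
#' @param seed integer seed.
#' @return list with `x`, `y`, `labels` and `truth` (`b_matrix`:
#'   `n_conditions x n_features` weight matrix, shared kernels, parameters).
#' @export
simulate_condition_set <- function(n_conditions = 5, separation = 1,
                                   n_discriminative = 2,
                                   n_trials_per_condition = 30,
                                   n_features = 8, trial_len = 400,
                                   fs = 200, snr_db = 10, filter_len = 25,
                                   seed = 1) {
  if (n_conditions < 2L) stop("need at least 2 conditions")
  if (separation < 0) stop("separation must be non-negative")
  set.seed(seed)
  g <- t(vapply(seq_len(n_features), function(j) smooth_fir(filter_len),
                numeric(filter_len)))
  base <- stats::runif(n_features, 0.9, 1.1)
  b_matrix <- matrix(rep(base, each = n_conditions), n_conditions, n_features)
  disc <- seq_len(min(n_discriminative, n_features))
  for (j in disc) {
    b_matrix[, j] <- base[j] + separation * (seq_len(n_conditions) - 1L) +
      if (j %% 2L == 0L) separation * 0.5 else 0
  }
  snr_lin <- if (is.finite(snr_db)) 10^(snr_db / 10) else Inf
  xs <- list(); ys <- list(); labels <- character(0)
  for (cc in seq_len(n_conditions)) {
    x <- array(stats::rnorm(n_trials_per_condition * n_features * trial_len),
               dim = c(n_trials_per_condition, n_features, trial_len))
    clean <- matrix(0, n_trials_per_condition, trial_len)
    for (k in seq_len(n_trials_per_condition)) {
      for (j in seq_len(n_features)) {
        clean[k, ] <- clean[k, ] + b_matrix[cc, j] * circ_conv(g[j, ], x[k, j, ])
      }
    }
    yc <- if (is.finite(snr_db)) {
      noise <- matrix(stats::rnorm(length(clean)), nrow(clean))
      clean + noise * sqrt(stats::var(as.vector(clean)) /
                             (stats::var(as.vector(noise)) * snr_lin))
    } else clean
    xs[[cc]] <- x
    ys[[cc]] <- yc
    labels <- c(labels, rep(sprintf("cond%d", cc), n_trials_per_condition))
  }
  data <- array(0, dim = c(n_conditions * n_trials_per_condition,
                           n_features, trial_len))
  ally <- matrix(0, n_conditions * n_trials_per_condition, trial_len)
  for (cc in seq_len(n_conditions)) {
    rows <- ((cc - 1L) * n_trials_per_condition + 1L):(cc * n_trials_per_condition)
    data[rows, , ] <- xs[[cc]]
    ally[rows, ] <- ys[[cc]]
  }
  list(
    x = feature_tensor(data, fs = fs, labels = labels),
    y = target_set(ally, fs = fs, modality = "synthetic"),
    labels = labels,
    truth = list(b_matrix = b_matrix, true_h = g, separation = separation,
                 snr_db = snr_db, seed = seed, fs = fs))
}
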