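#' Preprocessing configuration
#'
#' Collects the parameters of the preprocessing and feature-extraction chain.
#' Defaults follow common ECoG practice for decoding studies: a wide
#' broadband conditioning filter, a power-line notch, low-frequency
#' components (LFC) between 0.5 and 40 Hz, the high-frequency band envelope
#' (HFBE) from the 70-170 Hz band smoothed below 40 Hz, and a 200 Hz
#' analysis rate.
#'
#' @param broadband conditioning band-pass edges in Hz.
#' @param notch power-line notch frequency in Hz (`NA` disables it).
#' @param notch_q quality factor of the second-order IIR notch.
#' @param lfc low-frequency component band edges in Hz.
#' @param hfb high-frequency band edges in Hz for the envelope feature.
#' @param envelope_lp low-pass cut-off in Hz applied to the HFB envelope.
#' @param analysis_fs analysis sampling rate in Hz; all features and targets
#'   are resampled to this rate before model fitting.
#' @param order Butterworth design order (applied forward-backward, so the
#'   effective magnitude response is of twice this order).
#' @return A list of class `decode_config`.
#' @export
decode_config <- function(broadband = c(0.1, 200), notch = 60, notch_q = 30,
                          lfc = c(0.5, 40), hfb = c(70, 170),
                          envelope_lp = 40, analysis_fs = 200, order = 4) {
  structure(list(broadband = broadband, notch = notch, notch_q = notch_q,
                 lfc = lfc, hfb = hfb, envelope_lp = envelope_lp,
                 analysis_fs = analysis_fs, order = order),
            class = "decode_config")
}

# Zero-phase (forward-backward) filtering with full odd-symmetric reflection
# padding at both ends to suppress edge transients on short trials.
zp_filter <- function(flt, x) {
  n <- length(x)
  p <- n - 1L
  if (p < 1L) return(x)
  pre <- 2 * x[1L] - x[(p + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - p)]
  y <- signal::filtfilt(flt, c(pre, x, post))
  y[(p + 1L):(p + n)]
}

# Butterworth design as second-order sections (biquad cascade with the
# standard Butterworth Q factors). Polynomial transfer-function forms are
# numerically fragile when the cut-off sits orders of magnitude below
# Nyquist (0.1 Hz at 1 kHz); biquads stay well-conditioned.
butter_sos <- function(order, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (order %% 2L != 0L) stop("even filter order required")
  w0 <- pi * fc / (fs / 2)
  lapply(seq_len(order %/% 2L), function(k) {
    q <- 1 / (2 * sin((2 * k - 1) * pi / (2 * order)))
    alpha <- sin(w0) / (2 * q)
    cw <- cos(w0)
    if (type == "low") {
      b <- c((1 - cw) / 2, 1 - cw, (1 - cw) / 2)
    } else {
      b <- c((1 + cw) / 2, -(1 + cw), (1 + cw) / 2)
    }
    a <- c(1 + alpha, -2 * cw, 1 - alpha)
    signal::Arma(b = b / a[1L], a = a / a[1L])
  })
}

zp_sos <- function(sos, x) {
  for (bq in sos) x <- zp_filter(bq, x)
  x
}

# band-pass as a high-pass/low-pass biquad cascade
zp_bandpass <- function(x, fs, band, order) {
  zp_sos(butter_sos(order, band[2L], fs, "low"),
         zp_sos(butter_sos(order, band[1L], fs, "high"), x))
}

# Second-order IIR notch (constrained-pole biquad), applied zero-phase.
notch_coefs <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  signal::Arma(b = b, a = a)
}

check_band <- function(band, fs) {
  if (length(band) != 2L || band[1L] <= 0 || band[1L] >= band[2L]) {
    stop("band must be increasing positive edges [f_lo, f_hi]")
  }
  if (band[2L] >= fs / 2) {
    stop(sprintf("band edge %g Hz at or above Nyquist (%g Hz)", band[2L], fs / 2))
  }
}

apply_per_channel <- function(trials, fun) {
  d <- dim(trials$data)
  out <- trials$data
  for (k in seq_len(d[1L])) {
    for (j in seq_len(d[2L])) {
      out[k, j, ] <- fun(trials$data[k, j, ])
    }
  }
  trial_set(out, fs = trials$fs, labels = trials$labels,
            channel_ids = trials$channel_ids)
}

#' Broadband conditioning: band-pass plus power-line notch
#'
#' Applies a zero-phase Butterworth band-pass followed by a zero-phase IIR
#' notch to every channel of every trial. This is the first stage of the
#' preprocessing chain, run before re-referencing and feature extraction.
#'
#' @param trials a [trial_set()].
#' @param band band-pass edges in Hz.
#' @param notch_hz notch centre frequency in Hz; `NA` skips the notch.
#' @param order Butterworth design order.
#' @param notch_q notch quality factor.
#' @return A `trial_set` of the same shape.
#' @export
broadband_condition <- function(trials, band = c(0.1, 200), notch_hz = 60,
                                order = 4, notch_q = 30) {
  stopifnot(inherits(trials, "trial_set"))
  check_band(band, trials$fs)
  if (!is.na(notch_hz) && notch_hz >= trials$fs / 2) {
    stop(sprintf("notch frequency %g Hz at or above Nyquist", notch_hz))
  }
  nf <- if (is.na(notch_hz)) NULL else notch_coefs(notch_hz, trials$fs, notch_q)
  apply_per_channel(trials, function(x) {
    y <- zp_bandpass(x, trials$fs, band, order)
    if (!is.null(nf)) y <- zp_filter(nf, y)
    y
  })
}

#' Common average reference
#'
#' Subtracts, at every sample, the instantaneous mean across all channels
#' from each channel, reducing the influence of the shared reference
#' electrode. After re-referencing, the per-sample sum across channels is
#' exactly zero.
#'
#' @param trials a [trial_set()].
#' @return A `trial_set` of the same shape.
#' @export
car <- function(trials) {
  stopifnot(inherits(trials, "trial_set"))
  d <- dim(trials$data)
  out <- trials$data
  for (k in seq_len(d[1L])) {
    m <- colMeans(matrix(trials$data[k, , ], nrow = d[2L]))
    out[k, , ] <- sweep(matrix(trials$data[k, , ], nrow = d[2L]), 2L, m)
  }
  trial_set(out, fs = trials$fs, labels = trials$labels,
            channel_ids = trials$channel_ids)
}

#' Low-frequency components (LFC)
#'
#' Zero-phase Butterworth band-pass extracting the slow, phase-informative
#' part of the signal (0.5-40 Hz by default).
#'
#' @inheritParams broadband_condition
#' @return A `trial_set` of the same shape.
#' @export
extract_lfc <- function(trials, band = c(0.5, 40), order = 4) {
  stopifnot(inherits(trials, "trial_set"))
  check_band(band, trials$fs)
  apply_per_channel(trials, function(x) zp_bandpass(x, trials$fs, band, order))
}

# Analytic signal by frequency-domain construction of the Hilbert pair.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2L == 0L) {
    h[n / 2L + 1L] <- 1
    if (n > 2L) h[2L:(n / 2L)] <- 2
  } else {
    if (n > 1L) h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' High-frequency band envelope (HFBE)
#'
#' Band-passes each channel to the high-frequency band (70-170 Hz by
#' default), computes the magnitude of the analytic signal (Hilbert
#' envelope), and smooths it with a zero-phase Butterworth low-pass. The
#' envelope tracks amplitude modulation of high-gamma activity, a proxy for
#' local population firing.
#'
#' @inheritParams broadband_condition
#' @param lp_cutoff envelope low-pass cut-off in Hz.
#' @return A `trial_set` of the same shape containing envelopes.
#' @export
extract_hfbe <- function(trials, band = c(70, 170), lp_cutoff = 40, order = 4) {
  stopifnot(inherits(trials, "trial_set"))
  check_band(band, trials$fs)
  lp <- butter_sos(order, lp_cutoff, trials$fs, "low")
  apply_per_channel(trials, function(x) {
    bp <- zp_bandpass(x, trials$fs, band, order)
    zp_sos(lp, Mod(analytic_signal(bp)))
  })
}

resample_vector <- function(x, fs_in, fs_out) {
  n <- length(x)
  m <- round(n * fs_out / fs_in)
  if (fs_out == fs_in) return(x)
  d <- fs_in / fs_out
  if (abs(d - round(d)) < 1e-9) {
    d <- round(d)
    # anti-alias at 80% of the output Nyquist, zero-phase, then pick every
    # d-th sample
    lp <- butter_sos(8, 0.8 * fs_out / 2, fs_in, "low")
    y <- zp_sos(lp, x)[seq(1L, n, by = d)]
    return(y[seq_len(m)])
  }
  # non-integer ratio: Fourier-domain resampling of the (finite) trial
  X <- stats::fft(x)
  Y <- complex(m)
  half <- min(floor((n - 1) / 2), floor((m - 1) / 2))
  Y[1L] <- X[1L]
  if (half > 0) {
    Y[2L:(half + 1L)] <- X[2L:(half + 1L)]
    Y[(m - half + 1L):m] <- X[(n - half + 1L):n]
  }
  Re(stats::fft(Y, inverse = TRUE)) * (m / n) / m
}

#' Resample trials or targets to a new rate
#'
#' Downsamples with zero-phase anti-alias filtering (for integer decimation
#' factors) or Fourier-domain resampling (otherwise). The output length is
#' `round(n_samples * fs_out / fs)` per trial.
#'
#' @param x a [trial_set()] or [target_set()].
#' @param fs_out target sampling rate in Hz, at most the current rate.
#' @return The same type as `x`, at rate `fs_out`.
#' @export
resample_to <- function(x, fs_out) {
  if (!is.numeric(fs_out) || fs_out <= 0) stop("`fs_out` must be positive")
  if (fs_out > x$fs) stop("upsampling is not supported: fs_out exceeds fs")
  if (fs_out == x$fs) return(x)
  if (inherits(x, "trial_set")) {
    d <- dim(x$data)
    m <- round(d[3L] * fs_out / x$fs)
    out <- array(0, dim = c(d[1L], d[2L], m))
    for (k in seq_len(d[1L])) {
      for (j in seq_len(d[2L])) {
        out[k, j, ] <- resample_vector(x$data[k, j, ], x$fs, fs_out)
      }
    }
    trial_set(out, fs = fs_out, labels = x$labels, channel_ids = x$channel_ids)
  } else if (inherits(x, "target_set")) {
    m <- round(ncol(x$data) * fs_out / x$fs)
    out <- matrix(0, nrow(x$data), m)
    for (k in seq_len(nrow(x$data))) {
      out[k, ] <- resample_vector(x$data[k, ], x$fs, fs_out)
    }
    target_set(out, fs = fs_out, modality = x$modality)
  } else {
    stop("`x` must be a trial_set or target_set")
  }
}

#' Feature tensor
#'
#' Container for per-trial, per-feature time series at the analysis rate.
#' Each feature is a `(channel, band)` pair with band `"LFC"` or `"HFBE"`.
#'
#' @param data numeric array `[n_trials, n_features, n_samples]`.
#' @param fs analysis sampling rate in Hz.
#' @param feature_ids data frame with columns `channel` and `band`, one row
#'   per feature.
#' @param labels optional per-trial condition labels.
#' @return An object of class `feature_tensor`.
#' @export
feature_tensor <- function(data, fs, feature_ids = NULL, labels = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(1L, nrow(data), ncol(data)))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  d <- dim(data)
  if (is.null(feature_ids)) {
    feature_ids <- data.frame(channel = sprintf("f%02d", seq_len(d[2L])),
                              band = rep("LFC", d[2L]),
                              stringsAsFactors = FALSE)
  }
  if (nrow(feature_ids) != d[2L]) stop("feature_ids/feature count mismatch")
  if (!all(is.finite(data))) stop("feature tensor contains non-finite values")
  if (is.null(labels)) labels <- rep("cond1", d[1L])
  structure(list(data = data, fs = as.numeric(fs), feature_ids = feature_ids,
                 labels = as.character(labels)),
            class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<feature_tensor> %d trials x %d features x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat("bands:", paste(unique(x$feature_ids$band), collapse = ", "), "\n")
  invisible(x)
}

#' Extract decoding features from conditioned trials
#'
#' Computes the requested band features (LFC and/or HFBE) from trials that
#' have already been broadband-conditioned and re-referenced, then resamples
#' them to the analysis rate. Features are ordered all channels of the first
#' requested band, then all channels of the next.
#'
#' @param trials a conditioned, re-referenced [trial_set()].
#' @param bands character subset of `c("LFC", "HFBE")`.
#' @param config a [decode_config()].
#' @return A [feature_tensor()] at `config$analysis_fs`.
#' @export
build_features <- function(trials, bands = c("LFC", "HFBE"),
                           config = decode_config()) {
  stopifnot(inherits(trials, "trial_set"))
  if (!length(bands)) stop("at least one band must be requested")
  bands <- match.arg(bands, c("LFC", "HFBE"), several.ok = TRUE)
  pieces <- list()
  ids <- list()
  for (b in bands) {
    ts <- if (b == "LFC") {
      extract_lfc(trials, band = config$lfc, order = config$order)
    } else {
      extract_hfbe(trials, band = config$hfb, lp_cutoff = config$envelope_lp,
                   order = config$order)
    }
    ts <- resample_to(ts, config$analysis_fs)
    pieces[[b]] <- ts$data
    ids[[b]] <- data.frame(channel = trials$channel_ids, band = b,
                           stringsAsFactors = FALSE)
  }
  d1 <- dim(pieces[[1L]])
  data <- array(0, dim = c(d1[1L], length(bands) * d1[2L], d1[3L]))
  for (i in seq_along(bands)) {
    data[, ((i - 1L) * d1[2L] + 1L):(i * d1[2L]), ] <- pieces[[i]]
  }
  feature_tensor(data, fs = config$analysis_fs,
                 feature_ids = do.call(rbind, ids[bands]),
                 labels = trials$labels)
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper: broadband conditioning, common average reference,
#' band feature extraction and resampling to the analysis rate, in that
#' order. The paired target, if given, is resampled to the same rate.
#'
#' @param trials a raw [trial_set()].
#' @param targets optional paired [target_set()] at the recording rate.
#' @param bands bands to extract, see [build_features()].
#' @param config a [decode_config()].
#' @return A `feature_tensor`, or `list(x = feature_tensor, y = target_set)`
#'   when `targets` is supplied.
#' @export
preprocess_pipeline <- function(trials, targets = NULL,
                                bands = c("LFC", "HFBE"),
                                config = decode_config()) {
  cond <- broadband_condition(trials, band = config$broadband,
                              notch_hz = config$notch, order = config$order,
                              notch_q = config$notch_q)
  feats <- build_features(car(cond), bands = bands, config = config)
  if (is.null(targets)) return(feats)
  y <- resample_to(targets, config$analysis_fs)
  list(x = feats, y = y)
}
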