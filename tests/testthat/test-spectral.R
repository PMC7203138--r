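test_that("self cross-spectra are real, non-negative, and Pxy equals Pxx", {
  x <- white_features(6, 3, 64, seed = 10)
  y <- target_set(matrix(x$data[, 2, ], 6, 64), fs = 200)
  S <- cross_spectra(x, y)
  expect_equal(Im(S$Pxy[2, ]), rep(0, length(S$freqs)), tolerance = 1e-12)
  expect_equal(Re(S$Pxy[2, ]), S$Pxx[2, ], tolerance = 1e-12)
  expect_true(all(S$Pxx >= 0) && all(S$Pyy >= 0))
})

test_that("trial-as-window estimator matches a brute-force DFT oracle", {
  # pure 10 Hz tone with random trial phases in both signals
  set.seed(11)
  K <- 8; L <- 100; fs <- 200
  xarr <- array(0, dim = c(K, 1, L))
  ymat <- matrix(0, K, L)
  for (k in seq_len(K)) {
    ph <- runif(2, 0, 2 * pi)
    xarr[k, 1, ] <- sin(2 * pi * 10 * (0:(L - 1)) / fs + ph[1])
    ymat[k, ] <- sin(2 * pi * 10 * (0:(L - 1)) / fs + ph[2])
  }
  S <- cross_spectra(feature_tensor(xarr, fs = fs), target_set(ymat, fs = fs))
  ref <- manual_cross_spectra(xarr, ymat, fs)
  expect_equal(S$Pxx[1, ], ref$Pxx, tolerance = 1e-9)
  expect_equal(S$Pyy, ref$Pyy, tolerance = 1e-9)
  expect_equal(S$Pxy[1, ], ref$Pxy, tolerance = 1e-9)
  expect_equal(which.max(Mod(S$Pxy[1, ])), which(S$freqs == 10))

  # and on white noise with the boxcar/no-detrend variant
  set.seed(12)
  xa <- array(rnorm(5 * 1 * 32), dim = c(5, 1, 32))
  ym <- matrix(rnorm(5 * 32), 5, 32)
  S2 <- cross_spectra(feature_tensor(xa, fs = 64), target_set(ym, fs = 64),
                      window = "boxcar", detrend = "none")
  ref2 <- manual_cross_spectra(xa, ym, 64, window = "boxcar", detrend = "none")
  expect_equal(S2$Pxy[1, ], ref2$Pxy, tolerance = 1e-9)
})

test_that("squared coherence of independent noise shows the known 1/K bias", {
  K <- 200
  means <- vapply(1:5, function(s) {
    x <- white_features(K, 1, 64, seed = 100 + s)
    y <- white_target(K, 64, seed = 200 + s)
    mean(Mod(coherence(cross_spectra(x, y))$C)^2)
  }, 0)
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 1 / K), 3 * se + 1e-4)
})

test_that("coherence equals the pencil-and-paper DFT value on a 4-point toy", {
  xarr <- array(c(1, 0, 0, 0, 0, 1, 0, 0), dim = c(2, 1, 4))
  ymat <- matrix(c(1, 2, 0, 0, 0, 1, 2, 0), 2, 4, byrow = TRUE)
  S <- cross_spectra(feature_tensor(xarr, fs = 4), target_set(ymat, fs = 4),
                     window = "boxcar", detrend = "none")
  man <- manual_cross_spectra(xarr, ymat, 4, window = "boxcar", detrend = "none")
  Cman <- man$Pxy / sqrt(man$Pxx * man$Pyy)
  expect_equal(coherence(S)$C[1, ], Cman, tolerance = 1e-12)
})

test_that("squared coherence is bounded by Cauchy-Schwarz on any input", {
  for (s in 1:10) {
    x <- white_features(4, 2, 48, seed = 300 + s)
    y <- white_target(4, 48, seed = 400 + s)
    S <- cross_spectra(x, y)
    expect_true(all(Mod(S$Pxy)^2 <=
                      sweep(S$Pxx, 2, S$Pyy, `*`) * (1 + 1e-9)))
    C2 <- Mod(coherence(S)$C)^2
    expect_true(all(C2 >= 0 & C2 <= 1 + 1e-9))
  }
  # self-coherence is exactly 1 wherever there is power
  x <- white_features(4, 1, 48, seed = 311)
  y <- target_set(matrix(x$data[, 1, ], 4, 48), fs = 200)
  C <- coherence(cross_spectra(x, y))
  pw <- !attr(C, "flagged")[1, ]
  expect_equal(Mod(C$C[1, pw]), rep(1, sum(pw)), tolerance = 1e-9)
})

test_that("cross_spectra validates trial counts, alignment and pooling", {
  x <- white_features(1, 1, 32, seed = 12)
  y <- white_target(1, 32, seed = 13)
  expect_error(cross_spectra(x, y), "one realization")
  x2 <- white_features(4, 1, 32, seed = 14, labels = c("a", "a", "b", "b"))
  y2 <- white_target(4, 32, seed = 15)
  expect_error(cross_spectra(x2, y2), "mix several conditions")
  expect_s3_class(cross_spectra(x2, y2, force = TRUE), "spectra_set")
  y3 <- white_target(4, 48, seed = 16)
  expect_error(cross_spectra(x2, y3), "trial length")
})

test_that("Wiener filter recovers an exact circular delay system", {
  set.seed(17)
  K <- 16; L <- 64; d <- 5
  x <- array(rnorm(K * L), dim = c(K, 1, L))
  y <- t(sapply(seq_len(K), function(k) {
    c(x[k, 1, (L - d + 1):L], x[k, 1, 1:(L - d)])
  }))
  S <- cross_spectra(feature_tensor(x, fs = 100), target_set(y, fs = 100),
                     window = "boxcar", detrend = "none")
  fb <- wiener_filter(S, eps_rel = 0)
  expect_lt(max(Mod(fb$H[1, ] - exp(-2i * pi * (0:(L / 2)) * d / L))), 1e-6)
  expect_equal(fb$h[1, d + 1], 1, tolerance = 1e-9)
  expect_lt(max(abs(fb$h[1, -(d + 1)])), 1e-9)
})

test_that("Wiener filter recovers a 3-tap kernel under the default taper", {
  set.seed(18)
  K <- 64; L <- 512
  g <- c(0.7, -0.4, 0.2)
  x <- array(rnorm(K * L), dim = c(K, 1, L))
  y <- t(sapply(seq_len(K), function(k) circ_conv(g, x[k, 1, ])))
  S <- cross_spectra(feature_tensor(x, fs = 100), target_set(y, fs = 100))
  fb <- wiener_filter(S, eps_rel = 0)
  err <- sqrt(sum((fb$h[1, 1:3] - g)^2) + sum(fb$h[1, -(1:3)]^2)) /
    sqrt(sum(g^2))
  expect_lt(err, 1e-3)
})

test_that("identity system gives a unit filter and h is real", {
  x <- white_features(4, 2, 64, seed = 19)
  y <- target_set(matrix(x$data[, 1, ], 4, 64), fs = 200)
  fb <- wiener_filter(cross_spectra(x, y), eps_rel = 1e-8)
  expect_lt(max(Mod(fb$H[1, ] - 1)), 1e-6)
  expect_true(is.numeric(fb$h))
  # spectra at DC and Nyquist are forced real in the Hermitian extension
  expect_equal(Im(fb$H_full[, 1]), c(0, 0))
})

test_that("filter application equals time-domain circular convolution", {
  set.seed(20)
  L <- 40
  x <- white_features(3, 2, L, seed = 21)
  H <- matrix(complex(real = rnorm(2 * (L / 2 + 1)),
                      imaginary = rnorm(2 * (L / 2 + 1))), 2, L / 2 + 1)
  H[, 1] <- Re(H[, 1]); H[, L / 2 + 1] <- Re(H[, L / 2 + 1])
  Hf <- cohdecode:::hermitian_extend(H, L)
  h <- t(apply(Hf, 1, function(v) Re(stats::fft(v, inverse = TRUE)) / L))
  fb <- structure(list(freqs = (0:(L / 2)) * 200 / L, H = H, H_full = Hf,
                       h = h, fs = 200, nfft = L), class = "filter_bank")
  out <- apply_filterbank(x, fb)
  for (k in 1:3) for (j in 1:2) {
    expect_equal(out[k, j, ], circ_conv_direct(h[j, ], x$data[k, j, ]),
                 tolerance = 1e-10)
  }
  # identity and null filters
  H1 <- matrix(1 + 0i, 2, L / 2 + 1)
  fb1 <- structure(list(freqs = fb$freqs, H = H1,
                        H_full = cohdecode:::hermitian_extend(H1, L),
                        h = h, fs = 200, nfft = L), class = "filter_bank")
  expect_equal(apply_filterbank(x, fb1), x$data, tolerance = 1e-10)
  H0 <- matrix(0i, 2, L / 2 + 1)
  fb0 <- structure(list(freqs = fb$freqs, H = H0,
                        H_full = cohdecode:::hermitian_extend(H0, L),
                        h = h, fs = 200, nfft = L), class = "filter_bank")
  expect_true(all(apply_filterbank(x, fb0) == 0))
})

test_that("filters and predictions are scale-covariant", {
  sim <- simulate_feature_level(n_trials = 10, n_features = 3, trial_len = 64,
                                snr_db = 20, seed = 22)
  S1 <- cross_spectra(sim$x, sim$y)
  xs <- sim$x
  xs$data[, 2, ] <- 5 * xs$data[, 2, ]
  S2 <- cross_spectra(xs, sim$y)
  H1 <- wiener_filter(S1, eps_rel = 1e-8)$H
  H2 <- wiener_filter(S2, eps_rel = 1e-8)$H
  expect_equal(H2[2, ], H1[2, ] / 5, tolerance = 1e-9)
  # scaling the target scales the filters linearly
  ys <- sim$y; ys$data <- 3 * ys$data
  H3 <- wiener_filter(cross_spectra(sim$x, ys), eps_rel = 1e-8)$H
  expect_equal(H3, 3 * H1, tolerance = 1e-9)
})

test_that("filter estimates improve with the number of trials", {
  g <- c(0.6, -0.3, 0.3, 0.15)
  errs <- sapply(c(4, 16, 64), function(K) {
    mean(vapply(1:3, function(s) {
      set.seed(1000 * K + s)
      L <- 128
      x <- array(rnorm(K * L), dim = c(K, 1, L))
      y <- t(sapply(seq_len(K), function(k) circ_conv(g, x[k, 1, ])))
      fb <- wiener_filter(cross_spectra(feature_tensor(x, fs = 100),
                                        target_set(y, fs = 100)), eps_rel = 0)
      sqrt(sum((fb$h[1, seq_along(g)] - g)^2) +
             sum(fb$h[1, -seq_along(g)]^2))
    }, 0))
  })
  expect_true(all(diff(errs) < 0))
})

test_that("random-phase thresholds are bounded and maximal coherence exceeds them", {
  x <- white_features(6, 1, 48, seed = 23)
  y <- target_set(matrix(x$data[, 1, ], 6, 48), fs = 200)
  thr <- random_phase_threshold(x, y, alpha = 0.05, n_surrogates = 100, seed = 1)
  expect_true(all(thr >= 0 & thr <= 1))
  C2 <- Mod(coherence(cross_spectra(x, y))$C)^2
  # interior bins with power (at DC/Nyquist the sign-only surrogate null can
  # saturate at 1 with few trials)
  pw <- C2[1, ] > 1e-6
  pw[c(1, length(pw))] <- FALSE
  expect_true(all(C2[1, pw] > thr[1, pw]))

  expect_error(random_phase_threshold(x, target_set(matrix(0, 6, 48), fs = 200)),
               "all-zero target")
  expect_error(random_phase_threshold(x, y, alpha = 0.05, n_surrogates = 5),
               "n_surrogates")
})

test_that("coherence_significance returns one tidy row per feature-frequency bin", {
  x <- white_features(6, 2, 32, seed = 24)
  y <- white_target(6, 32, seed = 25)
  df <- coherence_significance(x, y, alpha = 0.05, n_surrogates = 60, seed = 2)
  expect_equal(nrow(df), 2 * 17)
  expect_true(all(c("feature_id", "freq_hz", "coh2", "threshold",
                    "significant") %in% names(df)))
  expect_true(all(df$coh2 >= 0 & df$coh2 <= 1 + 1e-9))
})
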