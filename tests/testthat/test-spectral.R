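test_that("DPSS tapers are orthonormal and spectrally concentrated", {
  n <- 256
  v <- dpss_tapers(n, 3, 5)
  expect_equal(dim(v), c(n, 5))
  expect_equal(crossprod(v), diag(5), tolerance = 1e-8)
  # first taper is a positive bell
  expect_true(all(v[, 1] > 0))
  # in-band energy concentration (half-bandwidth nw/n cycles/sample)
  pad <- 8192
  for (k in 1:5) {
    spec <- Mod(fft(c(v[, k], rep(0, pad - n))))^2
    f <- (0:(pad - 1)) / pad
    inband <- pmin(f, 1 - f) <= 3 / n
    conc <- sum(spec[inband]) / sum(spec)
    expect_gt(conc, if (k <= 2) 0.999 else 0.9)
  }
  expect_error(dpss_tapers(256, 3, 6), "2\\*nw - 1")
})

test_that("segmentation demeans and discards the trailing remainder", {
  rec <- lfp_recording(rnorm(3500), 1000)
  segs <- segment_lfp(rec)
  expect_equal(dim(segs), c(1000, 3))
  expect_equal(colMeans(segs), rep(0, 3), tolerance = 1e-12)

  const <- lfp_recording(rep(2.5, 1500), 1000)
  expect_true(all(segment_lfp(const) == 0))

  expect_error(segment_lfp(lfp_recording(rnorm(500), 1000)), "shorter than")
})

test_that("multi-taper PSD resolves a line and satisfies Parseval", {
  fs <- 500
  tt <- (0:(fs * 20 - 1)) / fs
  x <- sqrt(2) * sin(2 * pi * 10 * tt)
  ps <- mt_psd(lfp_recording(x, fs), spectral_params(freq_range = c(1, 90)))
  expect_gt(ps$value[ps$freq == 10] - ps$value[ps$freq == 30], 20)
  expect_equal(ps$freq[which.max(ps$value)], 10)

  set.seed(5)
  w <- lfp_recording(rnorm(fs * 60), fs)
  full <- mt_psd(w, spectral_params(freq_range = c(0, fs / 2 - 1)), bands = NULL)
  expect_equal(sum(full$linear) / var(w$samples), 1, tolerance = 0.05)

  # white-noise PSD is flat across bands (max/min band ratio < 1.5 dB)
  pw <- mt_psd(w)
  expect_lt(diff(range(pw$band_means)), 1.5)

  # determinism: identical inputs give bit-identical spectra
  expect_identical(mt_psd(w)$value, pw$value)

  expect_error(mt_psd(lfp_recording(rep(0, 2000), 1000)), "degenerate")
  expect_error(mt_psd(w, spectral_params(freq_range = c(1, 400))), "Nyquist")
})

test_that("coherence identity, symmetry and scale invariance hold", {
  set.seed(11)
  fs <- 500
  a <- lfp_recording(rnorm(fs * 10), fs, "a")
  b <- lfp_recording(rnorm(fs * 10), fs, "b")

  ci <- mt_coherence(a, a)
  expect_lt(max(abs(ci$value - 1)), 1e-9)

  cab <- mt_coherence(a, b)
  cba <- mt_coherence(b, a)
  expect_equal(cab$value, cba$value, tolerance = 1e-14)

  b2 <- lfp_recording(3.7 * b$samples, fs, "b")
  expect_lt(max(abs(mt_coherence(a, b2)$value - cab$value)), 1e-9)
  a2 <- lfp_recording(0.013 * a$samples, fs, "a")
  expect_lt(max(abs(mt_coherence(a2, b)$value - cab$value)), 1e-9)

  expect_error(mt_coherence(a, lfp_recording(rnorm(fs * 5), fs)), "durations")
  expect_error(mt_coherence(a, lfp_recording(rnorm(fs * 10), 2 * fs)),
               "sampling rates")
  z <- b$samples
  z[(2 * fs + 1):(3 * fs)] <- 0
  expect_error(mt_coherence(a, lfp_recording(z, fs, "zc")), "segment 3")
})

test_that("pooled coherence is nearly unbiased; per-segment carries 1/K bias", {
  set.seed(21)
  fs <- 500
  a <- lfp_recording(rnorm(fs * 60), fs, "a")
  b <- lfp_recording(rnorm(fs * 60), fs, "b")
  pooled <- mt_coherence(a, b)
  expect_lt(mean(pooled$value), 0.05)
  per <- mt_coherence(a, b, average = "per_segment")
  expect_gt(mean(per$value), 0.15) # ~1/n_tapers under independence
})

test_that("in-band coherence converges to the closed form at interior bins", {
  g <- gen_lfp_pair(source_band = c(4, 12), snr_a = 1, snr_b = 1,
                    fs = 500, duration = 100, seed = 9)
  co <- mt_coherence(g$a, g$b)
  interior <- co$freq >= 7 & co$freq <= 9 # clear of the +/-3 Hz edge smoothing
  expect_equal(mean(co$value[interior]), g$ground_truth$inband_coherence,
               tolerance = 0.05 / 0.25)
  far <- co$freq >= 30
  expect_lt(mean(co$value[far]), 0.05)
})

test_that("band summaries follow the half-open edge convention", {
  mk <- function(vals) {
    structure(list(freq = 1:90, value = vals, linear = NULL,
                   kind = "coherence", n_segments = 1,
                   params = spectral_params(), band_means = NULL),
              class = "mt_spectrum")
  }
  bands <- band_set()
  expect_equal(unname(band_summary(mk(rep(0.5, 90)), bands)), rep(0.5, 5))

  ind <- as.numeric(1:90 >= 4 & 1:90 < 12)
  bm <- band_summary(mk(ind), bands)
  expect_equal(unname(bm[c("delta", "theta", "beta")]), c(0, 1, 0))

  # ramp: band means equal direct arithmetic means of in-band grid values
  ramp <- seq(0, 1, length.out = 90)
  bm <- band_summary(mk(ramp), bands)
  f <- 1:90
  expect_equal(unname(bm["theta"]), mean(ramp[f >= 4 & f < 12]))
  expect_equal(unname(bm["high_gamma"]), mean(ramp[f >= 40 & f <= 90]))

  # the 90 Hz edge belongs to the final band
  top <- as.numeric(1:90 == 90)
  expect_equal(unname(band_summary(mk(top), bands)["high_gamma"]),
               1 / sum(f >= 40 & f <= 90))

  expect_error(band_summary(mk(ramp), band_set(high_gamma = c(40, 120))),
               "outside")
})
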