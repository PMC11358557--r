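make_trial <- function(x, rate, channels = NULL) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (is.null(channels)) channels <- paste0("CH", seq_len(nrow(x)))
  eeg_trial(x, rate = rate, channels = channels)
}

dominant_freq <- function(x, rate) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = rate), plot = FALSE,
                          taper = 0)
  sp$freq[which.max(sp$spec)]
}

test_that("resampling reaches the target rate and preserves tones", {
  t <- seq(0, 60 - 1 / 1000, by = 1 / 1000)
  tr <- make_trial(sin(2 * pi * 5 * t), 1000)
  out <- resample_trial(tr, 200)
  expect_equal(out$rate, 200)
  expect_equal(ncol(out$data), 12000, tolerance = 1e-9)
  expect_equal(dominant_freq(out$data[1, ], 200), 5, tolerance = 0.05)
  # identity when rates match; no upsampling
  expect_identical(resample_trial(tr, 1000)$data, tr$data)
  expect_error(resample_trial(tr, 2000), "upsampling")
})

test_that("central cropping uses the floor((n - len)/2) start", {
  tr <- make_trial(matrix(rnorm(2 * 48000), 2), 200)
  out <- crop_middle(tr, 60)
  expect_equal(ncol(out$data), 12000)
  # 240 s at 200 Hz: central minute spans 0-based samples [18000, 30000)
  expect_identical(out$data, tr$data[, 18001:30000])
  # a 10-sample trial cropped to 4 samples -> 0-based 3..6
  small <- make_trial(as.numeric(1:10), 1)
  expect_identical(as.vector(crop_middle(small, 4)$data), c(4, 5, 6, 7))
  expect_identical(crop_middle(small, 10)$data, small$data)
  expect_error(crop_middle(small, 11), "shorter")
})

test_that("band-pass design meets the pass/stop template", {
  spec <- design_bandpass("gamma", 200)
  h <- signal::freqz(spec$coefficients, 1, n = 2048, Fs = 200)
  mag <- 20 * log10(abs(h$h))
  inside <- h$f >= 34 & h$f <= 53
  expect_true(all(mag[inside] > -3))
  expect_lt(mag[which.min(abs(h$f - 25))], -40)
  expect_lt(mag[which.min(abs(h$f - 62))], -40)
  # taps symmetric (linear phase)
  expect_equal(spec$coefficients, rev(spec$coefficients), tolerance = 1e-12)
  # full band is a low-pass with unit DC gain
  lp <- design_bandpass("full", 200)
  expect_equal(sum(lp$coefficients), 1, tolerance = 0.01)
  expect_error(design_bandpass("x", 200, low_hz = 10, high_hz = 120), "Nyquist")
})

test_that("zero-phase application preserves passband tones and kills stopband", {
  rate <- 200
  t <- (0:11999) / rate
  s10 <- sin(2 * pi * 10 * t)
  tr <- make_trial(s10, rate)
  alpha <- apply_filter(tr, design_bandpass("alpha", rate))
  core <- 1000:11000 # away from edge transients
  expect_equal(sd(alpha$data[1, core]) / sd(s10[core]), 1, tolerance = 0.05)
  gamma <- apply_filter(tr, design_bandpass("gamma", rate))
  atten_db <- 20 * log10(sd(gamma$data[1, core]) / sd(s10[core]))
  expect_lt(atten_db, -40)
  # zero in, zero out; rate mismatch rejected
  z <- apply_filter(make_trial(numeric(500), rate), design_bandpass("alpha", rate))
  expect_true(all(z$data == 0))
  expect_error(apply_filter(make_trial(s10, 100), design_bandpass("alpha", 200)),
               "200")
})

test_that("filtering is linear", {
  rate <- 200
  set.seed(3)
  x <- rnorm(2000)
  y <- rnorm(2000)
  spec <- design_bandpass("beta", rate)
  f <- function(v) apply_filter(make_trial(v, rate), spec)$data[1, ]
  combo <- f(2 * x - 3 * y)
  expect_equal(combo, 2 * f(x) - 3 * f(y), tolerance = 1e-6)
})

test_that("z-scoring standardises per channel and is idempotent", {
  tr <- make_trial(rbind(c(1, 2, 3), c(10, 20, 30)), 1)
  z <- zscore_trial(tr)
  expect_equal(z$trial$data[1, ], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(zscore_trial(make_trial(c(10, 20), 1))$trial$data[1, ],
               c(-0.7071, 0.7071), tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(z$params$mean[1], 2, ignore_attr = TRUE)
  # all channels mean 0, sample sd 1
  expect_true(all(abs(rowMeans(z$trial$data)) < 1e-9))
  expect_true(all(abs(apply(z$trial$data, 1, sd) - 1) < 1e-9))
  # idempotence
  z2 <- zscore_trial(z$trial)
  expect_equal(z2$trial$data, z$trial$data, tolerance = 1e-9)
  expect_error(zscore_trial(make_trial(c(5, 5, 5), 1)), "CH1")
})

test_that("band extraction yields standardised, band-limited outputs", {
  set.seed(9)
  tr <- make_trial(matrix(rnorm(2 * 6000), 2), 200)
  out <- extract_bands(tr)
  expect_named(out, c("theta", "alpha", "beta", "gamma", "full"))
  sp <- stats::spec.pgram(stats::ts(out$gamma$data[1, ], frequency = 200),
                          plot = FALSE, taper = 0)
  in_band <- sum(sp$spec[sp$freq >= 32 & sp$freq <= 55]) / sum(sp$spec)
  expect_gt(in_band, 0.9)
  expect_length(extract_bands(tr, default_bands()[0, ]), 0)
  # non-adjacent bands share almost no power on broadband noise
  ov <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  spec_of <- function(x) stats::spec.pgram(stats::ts(x, frequency = 200),
                                           plot = FALSE, taper = 0)$spec
  expect_lt(ov(spec_of(out$theta$data[1, ]), spec_of(out$beta$data[1, ])), 0.1)
  expect_lt(ov(spec_of(out$alpha$data[1, ]), spec_of(out$gamma$data[1, ])), 0.1)
})
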