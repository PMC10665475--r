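test_that("piezo passthrough is the identity on valid traces", {
  tr <- channel_trace("piezo", rnorm(100), 100)
  expect_identical(piezo_passthrough(tr), tr)
})

test_that("bandpass keeps in-band tones and rejects out-of-band tones", {
  fs <- 100
  t <- seq(0, 60, by = 1 / fs)
  inband <- channel_trace("x", sin(2 * pi * 0.25 * t), fs)
  y <- bandpass(inband, 0.1, 0.7)
  mid <- 1000:5000 # away from filter edge transients
  expect_equal(length(y), length(inband))
  expect_lt(abs(max(abs(y$samples[mid])) - 1), 0.05)
  outband <- channel_trace("x", sin(2 * pi * 5 * t), fs)
  y2 <- bandpass(outband, 0.1, 0.7)
  expect_lt(max(abs(y2$samples[mid])), 0.1)
  zeros <- channel_trace("x", numeric(500), fs)
  expect_equal(bandpass(zeros, 0.1, 0.7)$samples, numeric(500))
  expect_error(bandpass(inband, 0.7, 0.1), "low_hz")
  expect_error(bandpass(inband, 0.1, 60), "fs/2")
})

test_that("PCA axis combination recovers collinear structure", {
  set.seed(2)
  x <- rnorm(500)
  tx <- channel_trace("acc1_x", x, 100)
  ty <- channel_trace("acc1_y", 2 * x, 100)
  tz <- channel_trace("acc1_z", -x, 100)
  pc <- pca_axis_combine(tx, ty, tz)
  # rank-1 cloud along (1,2,-1)/sqrt(6): scores proportional to centred x
  xc <- x - mean(x)
  expect_gt(abs(cor(pc$samples, xc)), 1 - 1e-12)
  expect_equal(sd(pc$samples), sd(xc) * sqrt(6), tolerance = 1e-9)
  expect_equal(attr(pc, "explained"), 1, tolerance = 1e-12)
})

test_that("PCA sign convention is deterministic and variance share sane", {
  set.seed(3)
  mk <- function(v) channel_trace("a", v, 100)
  # isotropic noise: PC1 share near 1/3
  n <- 20000
  pc <- pca_axis_combine(mk(rnorm(n)), mk(rnorm(n)), mk(rnorm(n)))
  expect_lt(abs(attr(pc, "explained") - 1 / 3), 0.02)
  # dominant-variance axis gets positive loading: flipping input flips output
  x <- rnorm(500)
  p1 <- pca_axis_combine(mk(3 * x), mk(rnorm(500, sd = 0.1)),
                         mk(rnorm(500, sd = 0.1)))
  expect_gt(cor(p1$samples, x), 0.99)
  # constant axes: zeros with warning-level log, not an error
  z <- mk(rep(1, 100))
  expect_equal(pca_axis_combine(z, z, z)$samples, numeric(100))
  expect_error(pca_axis_combine(mk(rnorm(10)), mk(rnorm(9)), mk(rnorm(10))),
               "length")
})

test_that("suppression factor follows its defining formula", {
  expect_equal(suppression_factor(c(1, 2, 3), c(0, 0, 0)), c(1, 1, 1))
  a1 <- c(2, 2, 2, 2)
  expect_equal(suppression_factor(a1, rep(mean(a1), 4)), rep(exp(-1), 4))
  set.seed(4)
  x1 <- abs(rnorm(16)); x2 <- abs(rnorm(16))
  expect_equal(suppression_factor(x1, x2), exp(-x2 / mean(x1)))
  expect_error(suppression_factor(numeric(16), x2), "degenerate")
  expect_error(suppression_factor(x1, x2[1:8]), "length")
})

test_that("spectral suppression matches the naive DFT oracle", {
  set.seed(5)
  for (n in c(8, 17, 32)) {
    x1 <- channel_trace("a", rnorm(n), 100)
    x2 <- channel_trace("b", rnorm(n), 100)
    res <- spectral_suppress(x1, x2)
    expect_lt(max(abs(res$denoised$samples -
                        spectral_suppress_naive(x1$samples, x2$samples))),
              1e-9)
  }
  # zero noise channel: identity
  x1 <- channel_trace("a", rnorm(64), 100)
  x2 <- channel_trace("b", numeric(64), 100)
  res <- spectral_suppress(x1, x2)
  expect_lt(max(abs(res$denoised$samples - x1$samples)), 1e-9)
  expect_equal(res$SF, rep(1, 64))
})

test_that("suppression invariants: SF range, monotonicity, energy, realness", {
  set.seed(6)
  x1 <- channel_trace("a", rnorm(64), 100)
  x2 <- channel_trace("b", rnorm(64, sd = 2), 100)
  res <- spectral_suppress(x1, x2)
  expect_true(all(res$SF > 0 & res$SF <= 1))
  expect_true(all(Mod(res$X_supp) <= Mod(res$X1) + 1e-12))
  expect_lte(sum(res$denoised$samples^2), sum(x1$samples^2) + 1e-9)
  expect_true(is.numeric(res$denoised$samples))
  # monotonicity: scaling the noise channel up never raises SF
  res2 <- spectral_suppress(x1, trace_with2(x2, 3 * x2$samples))
  expect_true(all(res2$SF <= res$SF + 1e-12))
  expect_true(all(Mod(res2$X_supp) <= Mod(res$X_supp) + 1e-12))
})

test_that("windowed suppression stays close to the one-shot transform", {
  set.seed(7)
  t <- seq(0, 20, by = 0.01)
  x1 <- channel_trace("a", sin(2 * pi * 0.3 * t) + rnorm(length(t), sd = 0.5),
                      100)
  x2 <- channel_trace("b", rnorm(length(t), sd = 0.5), 100)
  full <- spectral_suppress(x1, x2)$denoised$samples
  win <- spectral_suppress(x1, x2, window = 512)$denoised$samples
  expect_equal(length(win), length(full))
  expect_gt(cor(win, full), 0.9)
})

test_that("accelerometer denoising recovers respiration better than no suppression", {
  set.seed(8)
  fs <- 100
  t <- seq(0, 120, by = 1 / fs)
  clean <- sin(2 * pi * 0.25 * t)
  # shared vehicle noise in the simulator's style: resonances (one inside
  # the respiration band) over a weak broadband floor
  am <- 1 + 0.3 * sin(2 * pi * 0.02 * t + 1)
  noise <- 0.9 * am * sin(2 * pi * 0.45 * t + 0.7) +
    1.0 * sin(2 * pi * 1.8 * t + 2.1) +
    0.8 * sin(2 * pi * 11 * t + 0.3) +
    0.01 * rnorm(length(t))
  mk <- function(nm, v) channel_trace(nm, v, fs)
  acc1 <- list(mk("acc1_x", 0.9 * clean + noise),
               mk("acc1_y", 0.5 * clean + 0.8 * noise),
               mk("acc1_z", 0.2 * clean + 0.6 * noise))
  acc2 <- list(mk("acc2_x", noise + rnorm(length(t), sd = 0.02)),
               mk("acc2_y", 0.9 * noise + rnorm(length(t), sd = 0.02)),
               mk("acc2_z", 0.7 * noise + rnorm(length(t), sd = 0.02)))
  cfg <- pipeline_config()
  den <- denoise_accelerometer(acc1, acc2, cfg)
  raw <- pca_axis_combine(bandpass(acc1[[1]], 0.1, 0.7),
                          bandpass(acc1[[2]], 0.1, 0.7),
                          bandpass(acc1[[3]], 0.1, 0.7))
  expect_gt(abs(cor(den$samples, clean)), abs(cor(raw$samples, clean)))
  # zero noise channel with single-transform suppression: identity with
  # the band-passed PC1 of sensor 1
  zeros <- lapply(c("x", "y", "z"),
                  function(a) mk(paste0("acc2_", a), numeric(length(t))))
  cfg_full <- pipeline_config(suppress_window_s = 0)
  den0 <- denoise_accelerometer(acc1, zeros, cfg_full)
  expect_lt(max(abs(den0$samples - raw$samples)), 1e-9)
  # windowed variant: zero noise channel still reproduces the input
  den0w <- denoise_accelerometer(acc1, zeros, cfg)
  expect_lt(max(abs(den0w$samples - raw$samples)), 1e-6 * max(abs(raw$samples)))
  # mismatched rates refused
  acc2_bad <- lapply(acc2, function(tr) channel_trace(tr$name, tr$samples, 50))
  expect_error(denoise_accelerometer(acc1, acc2_bad, cfg), "rate")
})

test_that("resampling preserves length contract and spectral peak", {
  tr <- channel_trace("a", rnorm(1000), 100)
  up <- resample_to(tr, 200)
  expect_equal(length(up), 2000L)
  expect_equal(up$fs, 200)
  t <- seq(0, 100, by = 0.1)[-1001]
  slow <- channel_trace("v", sin(2 * pi * 0.3 * t), 10)
  up2 <- resample_to(slow, 200)
  expect_lt(abs(peak_frequency(up2$samples, 200) - 0.3),
            freq_bin(length(up2), 200) + 1e-12)
  expect_identical(resample_to(tr, 100), tr)
  expect_error(resample_to(tr, -5), "positive")
})

test_that("median filter matches the naive sliding-median oracle", {
  tr <- channel_trace("a", c(0, 0, 9, 0, 0), 10)
  expect_equal(median_filter(tr, 3)$samples, rep(0, 5))
  expect_identical(median_filter(tr, 1), tr)
  set.seed(9)
  for (k in c(3, 5, 9)) {
    x <- rnorm(200)
    tr <- channel_trace("a", x, 10)
    expect_equal(median_filter(tr, k)$samples, median_naive(x, k))
  }
  expect_error(median_filter(tr, 4), "odd")
})

test_that("amplitude normalization maps onto [-1, 1] and handles constants", {
  expect_equal(normalize_amplitude(channel_trace("a", c(-2, 0, 2), 1))$samples,
               c(-1, 0, 1))
  expect_equal(normalize_amplitude(channel_trace("a", c(0, 5), 1))$samples,
               c(-1, 1))
  expect_equal(normalize_amplitude(channel_trace("a", c(3, 3, 3), 1))$samples,
               c(0, 0, 0))
  set.seed(10)
  for (i in 1:20) {
    y <- normalize_amplitude(channel_trace("a", rnorm(50), 1))$samples
    expect_true(all(y >= -1 & y <= 1))
    expect_equal(range(y), c(-1, 1))
  }
})
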