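## transfer-function magnitude of the digital Butterworth at frequency f,
## evaluated directly from the coefficients (independent of filtfilt)
butter_gain <- function(fs, cutoff_hz, order, f) {
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  w <- 2 * pi * f / fs
  z <- exp(-1i * w * (seq_along(bf$b) - 1))
  Mod(sum(bf$b * z) / sum(bf$a * z))
}

## amplitude of the component at frequency f, by least squares on the
## central half of the series (filtfilt edges excluded)
component_amp <- function(x, fs, f) {
  n <- length(x)
  idx <- seq(floor(n / 4), floor(3 * n / 4))
  t <- (idx - 1) / fs
  fit <- lm.fit(cbind(1, sin(2 * pi * f * t), cos(2 * pi * f * t)), x[idx])
  sqrt(sum(coef(fit)[2:3]^2))
}

test_that("low-pass filter preserves DC and the passband, kills the stopband", {
  expect_equal(lowpass_filter(rep(5, 200), fs = 100), rep(5, 200))

  t <- seq(0, 60, by = 0.01)
  x <- sin(2 * pi * 0.1 * t) + sin(2 * pi * 10 * t)
  y <- lowpass_filter(x, fs = 100, cutoff_hz = 2)
  ## forward-backward filtering squares the one-way magnitude response
  expect_equal(component_amp(y, 100, 0.1),
               butter_gain(100, 2, 4, 0.1)^2, tolerance = 0.01)
  amp10 <- component_amp(y, 100, 10)
  gain10 <- butter_gain(100, 2, 4, 10)^2
  expect_lt(amp10, 10 * gain10 + 1e-10)
  expect_lt(amp10, 1e-4)
})

test_that("low-pass filter rejects impossible requests", {
  expect_error(lowpass_filter(rnorm(3), fs = 100), "too short")
  expect_error(lowpass_filter(rnorm(100), fs = 4, cutoff_hz = 2), "Nyquist")
})

test_that("filtering is idempotent for band-limited signals", {
  t <- seq(0, 120, by = 0.125)
  x <- 5 + 0.5 * sin(2 * pi * 0.03 * t)
  once <- lowpass_filter(x, fs = 8)
  twice <- lowpass_filter(once, fs = 8)
  expect_lt(max(abs(twice - once)) / diff(range(once)), 0.01)
})

test_that("tachogram resampling honours constants, linearity and knots", {
  const <- tibble::tibble(beat_time = seq(0.8, 60, by = 0.8), rr = 0.8)
  g <- resample_rr(const)
  expect_true(all(g$rr == 0.8))
  expect_equal(median(diff(g$t)), 0.25)

  two <- tibble::tibble(beat_time = c(0, 1), rr = c(0.6, 1.0))
  g2 <- resample_rr(two, grid_hz = 2, method = "linear")
  expect_equal(g2$rr[g2$t == 0.5], 0.8)

  set.seed(11)
  bt <- cumsum(0.8 + 0.1 * sin(seq_len(100) / 5))
  beats <- tibble::tibble(beat_time = bt, rr = diff(c(0, bt)))
  sp <- splinefun(beats$beat_time, beats$rr, method = "monoH.FC")
  expect_equal(sp(beats$beat_time), beats$rr, tolerance = 1e-9)
  g3 <- resample_rr(beats)
  expect_true(all(g3$rr >= min(beats$rr) - 1e-12))
  expect_true(all(g3$rr <= max(beats$rr) + 1e-12))

  expect_error(resample_rr(beats[1, ]), "at least 2 beats")
})

test_that("min-max normalization maps the register span onto [0, 1]", {
  p <- norm_params(c(1, 3))
  expect_equal(normalize_minmax(c(1, 2, 3), p), c(0, 0.5, 1))
  expect_equal(normalize_minmax(3, p), 1)
  expect_error(norm_params(rep(2, 5)), "degenerate")
})

test_that("normalization is invariant to affine rescaling of the register", {
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(50)
    a <- runif(1, 0.1, 5)
    b <- rnorm(1)
    expect_equal(normalize_minmax(a * x + b, norm_params(a * x + b)),
                 normalize_minmax(x, norm_params(x)),
                 tolerance = 1e-12)
  }
})

test_that("preprocessing attaches grids, norm params and band boundaries", {
  reg <- generate_register(synth_schedule(c(Basal = 60, Stress = 60)), seed = 2)
  pre <- preprocess_register(reg)
  expect_s3_class(pre$rr_grid, "tbl_df")
  expect_equal(median(diff(pre$rr_grid$t)), 0.25)
  expect_s3_class(pre$norm, "norm_params")
  expect_s3_class(pre$bands, "rr_band_boundaries")
  expect_equal(nrow(pre$eda_filt), nrow(reg$eda))
  ## whole-register extrema define the normalization
  expect_equal(pre$norm$x_min, min(pre$rr_grid$rr))
  expect_equal(pre$norm$x_max, max(pre$rr_grid$rr))
})
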