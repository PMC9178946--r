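test_that("the lag-1 embedding and centroid follow the definition", {
  p <- poincare_plot(c(0.8, 0.9, 1.0, 1.1))
  expect_equal(p$points$x, c(0.8, 0.9, 1.0))
  expect_equal(p$points$y, c(0.9, 1.0, 1.1))
  expect_equal(p$x_c, mean(c(0.8, 0.9, 1.0)))

  pc <- poincare_plot(rep(0.8, 5))
  expect_true(all(pc$points$x == 0.8) && all(pc$points$y == 0.8))

  expect_error(poincare_plot(0.8), "at least 2 beats")
})

test_that("alternating sequences reproduce the hand-computed descriptors", {
  ## 5 beats -> 4 points, two at (0.8, 1.0) and two at (1.0, 0.8):
  ## centroid (0.9, 0.9), SD1c = 0.2/sqrt(2), SD2c = 0,
  ## SD1b = sqrt(4 * 0.04 / 8) = SD1c, Ce = Cd = 0.5
  for (n_beats in c(5, 9)) {
    rr <- rep(c(0.8, 1.0), length.out = n_beats)
    d <- poincare_descriptors(rr)
    expect_equal(d$SD1c, 0.2 / sqrt(2), tolerance = 1e-12)
    expect_equal(d$SD2c, 0, tolerance = 1e-12)
    expect_equal(d$SD1b, 0.2 / sqrt(2), tolerance = 1e-12)
    expect_equal(d$Ce, 0.5)
    expect_equal(d$Cd, 0.5)
    expect_equal(d$n_e + d$n_d, n_beats - 1)
  }
})

test_that("a constant sequence degenerates with undefined contributions", {
  d <- poincare_descriptors(rep(0.8, 10))
  expect_equal(d$SD1c, 0)
  expect_equal(d$SD2c, 0)
  expect_equal(d$SD1b, 0)
  expect_equal(d$n_e, 0)
  expect_equal(d$n_d, 0)
  expect_true(is.na(d$Ce))
  expect_true(is.na(d$Cd))
})

test_that("decomposition identities hold to machine precision", {
  set.seed(29)
  for (i in 1:50) {
    d <- poincare_descriptors(random_rr(sample(5:60, 1)))
    expect_equal(d$SD1e^2 + d$SD1d^2, d$SD1b^2, tolerance = 1e-14)
    expect_equal(d$Ce + d$Cd, 1, tolerance = 1e-12)
    expect_lte(d$n_e + d$n_d, length(random_rr(10)) * 100)  # counts finite
  }
})

test_that("descriptors match the literal loop-based oracle on short sequences", {
  set.seed(31)
  for (i in 1:30) {
    rr <- random_rr(sample(3:10, 1))
    d <- poincare_descriptors(rr)
    o <- poincare_oracle(rr)
    for (f in names(o)) expect_equal(d[[f]], o[[f]], tolerance = 1e-12)
  }
})

test_that("time reversal swaps accelerations and decelerations", {
  set.seed(37)
  rr <- random_rr(40)
  d <- poincare_descriptors(rr)
  dr <- poincare_descriptors(rev(rr))
  expect_equal(dr$n_e, d$n_d)
  expect_equal(dr$n_d, d$n_e)
  expect_equal(dr$SD1e, d$SD1d, tolerance = 1e-14)
  expect_equal(dr$SD1d, d$SD1e, tolerance = 1e-14)
  expect_equal(dr$SD1b, d$SD1b, tolerance = 1e-14)
  expect_equal(dr$SD1c, d$SD1c, tolerance = 1e-14)
  expect_equal(dr$SD2c, d$SD2c, tolerance = 1e-14)
})

test_that("SD1b approaches SD1c for long stationary series", {
  set.seed(41)
  n <- 1e5
  rr <- 0.8 + as.numeric(stats::filter(rnorm(n, 0, 0.02), 0.5,
                                       method = "recursive"))
  d <- poincare_descriptors(rr)
  expect_lt(abs(d$SD1b - d$SD1c) / d$SD1c, 0.01)
})
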