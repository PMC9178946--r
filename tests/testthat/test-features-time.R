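grid_of <- function(t, v, name) {
  out <- tibble::tibble(t = t)
  out[[name]] <- v
  out
}

test_that("constant and linear RR windows give the stated degenerate values", {
  t <- seq(0, 19.75, by = 0.25)
  eda <- grid_of(t, 5 + 0.01 * t, "eda")
  np <- norm_params(c(0.5, 1.0))

  f <- time_features(grid_of(t, rep(0.8, length(t)), "rr"), eda, np)
  expect_equal(f$RR_Max, 0.8)
  expect_equal(f$RR_Min, 0.8)
  expect_equal(f$RR_Range, 0)
  expect_equal(f$RR_Mean, 0.8)
  expect_equal(f$RR_Slope, 0)
  expect_equal(f[["RR/RR_SurfDiff"]], 0)
  expect_equal(f$RR_Norm_Mean, (0.8 - 0.5) / 0.5)

  a <- 0.004
  f2 <- time_features(grid_of(t, 0.7 + a * t, "rr"), eda, np)
  expect_equal(f2$RR_Slope, a, tolerance = 1e-12)
  expect_equal(f2[["RR/RR_SurfDiff"]], 0, tolerance = 1e-12)
  expect_equal(f2$EDA_Slope, 0.01, tolerance = 1e-12)
})

test_that("RR range identity and normalised bounds hold on random windows", {
  set.seed(8)
  t <- seq(0, 19.75, by = 0.25)
  for (i in 1:15) {
    rr <- 0.8 + cumsum(rnorm(length(t), 0, 0.01))
    np <- norm_params(range(rr) + c(-0.05, 0.05))
    f <- time_features(grid_of(t, rr, "rr"), grid_of(t, rnorm(length(t), 5), "eda"), np)
    expect_equal(f$RR_Range, f$RR_Max - f$RR_Min)
    expect_lte(f$RR_Min, f$RR_Mean)
    expect_lte(f$RR_Mean, f$RR_Max)
    expect_true(all(c(f$RR_Norm_Max, f$RR_Norm_Min, f$RR_Norm_Mean) >= 0))
    expect_true(all(c(f$RR_Norm_Max, f$RR_Norm_Min, f$RR_Norm_Mean) <= 1))
    expect_gte(f[["RR/RR_SurfDiff"]], 0)
    expect_gte(f[["EDA/EDA_SurfDiff"]], 0)
    expect_gte(f[["EDA/RR_SurfDiff"]], 0)
  }
})

test_that("residual surfaces agree with a dense 1 kHz trapezoidal oracle", {
  t <- seq(0, 19.875, by = 0.125)  # 8 Hz EDA grid
  ## ramp plus a unit rectangular bump of width 2 s centred in the window
  eda <- t * 0.1 + as.numeric(t >= 9 & t < 11)
  np <- norm_params(c(0.5, 1.0))
  rrt <- seq(0, 19.75, by = 0.25)
  f <- time_features(grid_of(rrt, rep(0.8, length(rrt)), "rr"),
                     grid_of(t, eda, "eda"), np)

  line <- lm(eda ~ t)
  td <- seq(0, max(t), by = 1e-4)
  resid_d <- approx(t, eda, xout = td)$y -
    unname(predict(line, newdata = data.frame(t = td)))
  oracle <- unname(pracma::trapz(td, abs(resid_d)))
  expect_equal(f[["EDA/EDA_SurfDiff"]], oracle, tolerance = 1e-6)

  ## random smooth signals, all three surfaces
  set.seed(21)
  for (i in 1:10) {
    rr <- 0.8 + 0.05 * sin(2 * pi * 0.1 * rrt + runif(1, 0, 2 * pi)) +
      cumsum(rnorm(length(rrt), 0, 0.003))
    ed <- 5 + 0.3 * sin(2 * pi * 0.07 * t + runif(1, 0, 2 * pi))
    fx <- time_features(grid_of(rrt, rr, "rr"), grid_of(t, ed, "eda"),
                        norm_params(range(rr)))
    rr_line <- lm(rr ~ rrt)
    td2 <- seq(0, max(rrt), by = 1e-4)
    res <- approx(rrt, rr, xout = td2)$y -
      unname(predict(rr_line, newdata = data.frame(rrt = td2)))
    expect_equal(fx[["RR/RR_SurfDiff"]], unname(pracma::trapz(td2, abs(res))),
                 tolerance = 1e-6)
  }
})

test_that("time features scale equivariantly with the RR units", {
  set.seed(13)
  t <- seq(0, 19.75, by = 0.25)
  rr <- 0.8 + cumsum(rnorm(length(t), 0, 0.01))
  eda <- grid_of(t, rnorm(length(t), 5), "eda")
  c_scale <- 2.5
  f1 <- time_features(grid_of(t, rr, "rr"), eda, norm_params(range(rr)))
  f2 <- time_features(grid_of(t, c_scale * rr, "rr"), eda,
                      norm_params(range(c_scale * rr)))
  for (col in c("RR_Max", "RR_Min", "RR_Range", "RR_Mean", "RR_Slope")) {
    expect_equal(f2[[col]], c_scale * f1[[col]], tolerance = 1e-12)
  }
  for (col in c("RR_Norm_Max", "RR_Norm_Min", "RR_Norm_Range", "RR_Norm_Mean")) {
    expect_equal(f2[[col]], f1[[col]], tolerance = 1e-12)
  }
})

test_that("rolling statistics use an expanding trailing span of four windows", {
  feats <- tibble::tibble(a = c(1, 2, 3, 4, 5), b = rep(7, 5))
  rs <- rolling_feature_stats(feats)
  expect_equal(ncol(rs), 4)
  expect_named(rs, c("a_Avg", "a_Std", "b_Avg", "b_Std"))
  expect_equal(rs$a_Avg[1], 1)           # first window: own value
  expect_equal(rs$a_Std[1], 0)
  expect_equal(rs$a_Avg[4], mean(1:4))   # fourth window: {1,2,3,4}
  expect_equal(rs$a_Std[4], sd(1:4))
  expect_equal(rs$a_Avg[5], mean(2:5))   # trailing four only
  expect_true(all(rs$b_Avg == 7))
  expect_true(all(rs$b_Std == 0))
})
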