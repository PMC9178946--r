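## rank-formula Friedman statistic, written independently of friedman_test
friedman_oracle <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  r <- t(apply(m, 1, rank))
  12 / (n * k * (k + 1)) * sum((colSums(r) - n * (k + 1) / 2)^2)
}

test_that("Friedman statistic matches its closed forms and an oracle", {
  ## identical algorithms: statistic 0, p 1
  m0 <- matrix(rep(c(0.9, 0.8, 0.7), times = 3), nrow = 3)  # rows constant
  f0 <- friedman_test(m0)
  expect_equal(f0$statistic, 0)
  expect_equal(f0$p_value, 1)

  ## 3 algorithms strictly ordered in all 100 blocks: 12/(n k (k+1)) * sum
  ## over ranks 1..3 gives exactly 2n = 200
  set.seed(83)
  m1 <- cbind(a = runif(100) + 2, b = runif(100) + 1, c = runif(100))
  expect_equal(friedman_test(m1)$statistic, 200)

  ## random matrices against the independent rank formula
  for (i in 1:10) {
    m <- matrix(rnorm(5 * 20), ncol = 5)
    expect_equal(friedman_test(m)$statistic, friedman_oracle(m),
                 tolerance = 1e-12)
  }

  ## two algorithms reduce to a sign-test-like statistic
  m2 <- matrix(rnorm(40), ncol = 2)
  expect_equal(friedman_test(m2)$statistic, friedman_oracle(m2),
               tolerance = 1e-12)
  expect_error(friedman_test(matrix(1:10, ncol = 1)), "2 algorithms")
})

test_that("degenerate difference vectors give the stated point-mass verdicts", {
  b0 <- bc_ttest(rep(0, 100))
  expect_equal(b0$p_rope, 1)
  expect_equal(b0$verdict, "equivalent")

  b1 <- bc_ttest(rnorm(100, 0.05, 1e-9))
  expect_gt(b1$p_right, 0.999)
  expect_equal(b1$verdict, "row_better")
})

test_that("posterior masses match Student-t quadrature and sum to one", {
  set.seed(89)
  for (i in 1:25) {
    x <- rnorm(100, rnorm(1, 0, 0.02), runif(1, 0.005, 0.05))
    bc <- bc_ttest(x)
    expect_equal(bc$p_left + bc$p_rope + bc$p_right, 1, tolerance = 1e-9)
    dens <- function(u) dt((u - bc$mu_hat) / bc$scale, bc$dof) / bc$scale
    q_left <- integrate(dens, -Inf, -bc$rope, rel.tol = 1e-10)$value
    q_rope <- integrate(dens, -bc$rope, bc$rope, rel.tol = 1e-10)$value
    expect_equal(bc$p_left, q_left, tolerance = 1e-6)
    expect_equal(bc$p_rope, q_rope, tolerance = 1e-6)
  }
})

test_that("swapping the comparison negates the location and mirrors masses", {
  set.seed(97)
  x <- rnorm(60, 0.01, 0.03)
  a <- bc_ttest(x)
  b <- bc_ttest(-x)
  expect_equal(b$mu_hat, -a$mu_hat)
  expect_equal(b$p_left, a$p_right, tolerance = 1e-12)
  expect_equal(b$p_right, a$p_left, tolerance = 1e-12)
})

test_that("as rho tends to zero the posterior approaches the standard t", {
  set.seed(101)
  x <- rnorm(50, 0.02, 0.04)
  bc <- bc_ttest(x, rho = 1e-9)
  expect_equal(bc$scale, sd(x) / sqrt(length(x)), tolerance = 1e-6)
})

test_that("shifting all differences shifts the posterior location exactly", {
  set.seed(103)
  x <- rnorm(40, 0, 0.02)
  expect_equal(bc_ttest(x + 0.015)$mu_hat, bc_ttest(x)$mu_hat + 0.015,
               tolerance = 1e-12)
})

test_that("the comparison matrix is antisymmetric and decisive when it should be", {
  tab <- make_separable_table(n_per_class = 20)
  ## chance-level reference: predicts a fixed class whatever the input
  const_spec <- list(
    id = "Const",
    fit = function(x, y) levels(y),
    predict = function(m, x) {
      p <- matrix(1e-6, nrow(x), length(m), dimnames = list(NULL, m))
      p[, 2] <- 1
      p
    }
  )
  algs <- c(rresp_algorithms(c("DT", "NB")), list(Const = const_spec))
  cv <- run_cv(tab, algs, runs = 2, folds = 5, seed = 19)
  cmp <- build_comparison_matrix(cv)
  cells <- tidy(cmp)

  self_like <- cells[cells$row == "DT" & cells$column == "NB", ]
  ab <- cells[cells$row == "DT" & cells$column == "Const", ]
  ba <- cells[cells$row == "Const" & cells$column == "DT", ]
  expect_equal(ab$p_right, ba$p_left, tolerance = 1e-12)
  expect_equal(ab$verdict, "row_better")
  expect_gt(ab$probability, 0.99)
  expect_equal(ba$verdict, "column_better")

  ## identical metrics (both perfect learners here) fall in the ROPE
  expect_equal(self_like$verdict, "equivalent")
})
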