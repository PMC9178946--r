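## small internal helpers

## integral of |y(t)| for the piecewise-linear signal through (t, y):
## trapezoid per segment, split exactly at zero crossings so the result is
## the true integral of the absolute interpolant, not of |values| only
abs_trapz <- function(t, y) {
  n <- length(t)
  t1 <- t[-n]; t2 <- t[-1]
  y1 <- y[-n]; y2 <- y[-1]
  cross <- (y1 * y2) < 0
  area <- (abs(y1) + abs(y2)) / 2 * (t2 - t1)
  if (any(cross)) {
    tc <- t1[cross] - y1[cross] * (t2[cross] - t1[cross]) / (y2[cross] - y1[cross])
    area[cross] <- abs(y1[cross]) * (tc - t1[cross]) / 2 +
      abs(y2[cross]) * (t2[cross] - tc) / 2
  }
  sum(area)
}

## OLS slope and intercept of y ~ t without lm() overhead
ols_line <- function(t, y) {
  tb <- mean(t)
  yb <- mean(y)
  dt <- t - tb
  denom <- sum(dt^2)
  if (denom <= 0) stop("degenerate window: time values are constant", call. = FALSE)
  slope <- sum(dt * (y - yb)) / denom
  c(intercept = yb - slope * tb, slope = slope)
}

## deterministic sub-seed derivation, kept well below 2^31
derive_seed <- function(seed, ...) {
  parts <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (p in parts) s <- (s * 69069 + as.numeric(p) + 1) %% 2147483647
  as.integer(s)
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
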