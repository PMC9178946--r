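## deterministic flat register: constant RR and EDA, no noise -- useful for
## window-count arithmetic and degenerate-feature checks
## rr = 0.5 divides integer durations, so the beat train spans [0, total_s]
make_flat_register <- function(total_s, rr = 0.5, eda = 5, eda_fs = 8,
                               annotations = NULL) {
  reg <- physio_register(
    "flat",
    eda = tibble::tibble(t = seq(0, total_s, by = 1 / eda_fs), eda = eda),
    rr_beats = tibble::tibble(beat_time = seq(0, total_s, by = rr), rr = rr),
    annotations = annotations
  )
  ## constant RR: normalization is undefined by design, silence the notice
  suppressWarnings(preprocess_register(reg))
}

## small labelled table where the class is a deterministic threshold of one
## feature; remaining features are noise
make_separable_table <- function(n_per_class = 20, n_noise = 4, seed = 42) {
  set.seed(seed)
  lv <- rresp_classes()
  y <- factor(rep(lv, each = n_per_class), levels = lv)
  x1 <- as.integer(y) + runif(length(y), -0.3, 0.3)  # class bands never overlap
  noise <- matrix(rnorm(length(y) * n_noise), ncol = n_noise)
  colnames(noise) <- paste0("noise", seq_len(n_noise))
  out <- tibble::as_tibble(cbind(tibble::tibble(x1 = x1), noise))
  out$label <- y
  out
}

## literal loop transcription of the Poincare descriptor equations, kept
## deliberately naive as an independent oracle
poincare_oracle <- function(rr) {
  n_beats <- length(rr)
  x <- c(); y <- c()
  for (i in 1:(n_beats - 1)) {
    x <- c(x, rr[i])
    y <- c(y, rr[i + 1])
  }
  n <- length(x)
  x_c <- sum(x) / n
  y_c <- sum(y) / n
  d1 <- c(); d2 <- c()
  for (i in 1:n) {
    d1 <- c(d1, abs((x[i] - x_c) - (y[i] - y_c)) / sqrt(2))
    d2 <- c(d2, abs((x[i] - x_c) + (y[i] - y_c)) / sqrt(2))
  }
  sd1c <- sqrt(sum(d1^2) / n)
  sd2c <- sqrt(sum(d2^2) / n)
  s_all <- 0; s_e <- 0; s_d <- 0; n_e <- 0; n_d <- 0
  for (i in 1:n) {
    s_all <- s_all + (x[i] - y[i])^2
    if (y[i] > x[i]) {
      s_e <- s_e + (x[i] - y[i])^2
      n_e <- n_e + 1
    } else if (y[i] < x[i]) {
      s_d <- s_d + (x[i] - y[i])^2
      n_d <- n_d + 1
    }
  }
  sd1b <- sqrt(s_all / (2 * n))
  sd1e <- sqrt(s_e / (2 * n))
  sd1d <- sqrt(s_d / (2 * n))
  list(SD1c = sd1c, SD2c = sd2c, SD1b = sd1b, SD1e = sd1e, SD1d = sd1d,
       n_e = n_e, n_d = n_d,
       Ce = if (sd1b > 0) sd1e^2 / sd1b^2 else NA_real_,
       Cd = if (sd1b > 0) sd1d^2 / sd1b^2 else NA_real_)
}

## random RR sequence with non-degenerate lag-1 variability
random_rr <- function(n = 50, mean = 0.8, sd = 0.05) {
  rr <- rnorm(n, mean, sd)
  pmax(rr, 0.3)
}

## exhaustive merit maximisation over all non-empty subsets, on the same
## correlation structures the search uses
exhaustive_best_merit <- function(su_cf, su_ff) {
  p <- length(su_cf)
  best <- 0
  for (mask in 1:(2^p - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    m <- cfs_merit(idx, su_cf, su_ff)
    if (m > best) best <- m
  }
  best
}

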