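## the 13 per-window time-domain feature names, in canonical order
TIME_FEATURES <- c(
  "RR_Max", "RR_Min", "RR_Range", "RR_Mean",
  "RR_Norm_Max", "RR_Norm_Min", "RR_Norm_Range", "RR_Norm_Mean",
  "RR_Slope", "EDA_Slope",
  "EDA/EDA_SurfDiff", "EDA/RR_SurfDiff", "RR/RR_SurfDiff"
)

#' Time-domain features of one analysis window
#'
#' Extremes and mean of the windowed RR grid (raw and min-max normalised
#' with register-level parameters), least-squares slopes of RR and EDA
#' against time, and three residual "surfaces": the time-integral of the
#' absolute difference between a signal and a linear regression over the
#' window (trapezoidal rule). `RR/RR_SurfDiff` uses RR against its own
#' regression, `EDA/EDA_SurfDiff` EDA against its own, and
#' `EDA/RR_SurfDiff` the RR signal against the EDA's regression with both
#' series co-sampled on the RR grid.
#'
#' @param rr_grid Window slice of the even RR grid (tibble `t`, `rr`).
#' @param eda_grid Window slice of the filtered EDA (tibble `t`, `eda`).
#' @param norm Register-level [norm_params()] for the RR signal.
#' @return One-row tibble with the 13 named features.
#' @export
time_features <- function(rr_grid, eda_grid, norm) {
  if (nrow(rr_grid) < 2 || nrow(eda_grid) < 2) {
    stop("degenerate window: need at least 2 samples of each signal",
         call. = FALSE)
  }
  rr <- rr_grid$rr
  rt <- rr_grid$t
  rr_n <- normalize_minmax(rr, norm)

  rr_line <- ols_line(rt, rr)
  eda_line <- ols_line(eda_grid$t, eda_grid$eda)
  rr_fit <- rr_line[1] + rr_line[2] * rt
  eda_fit <- eda_line[1] + eda_line[2] * eda_grid$t
  ## EDA regression evaluated on the RR grid, refit from co-sampled EDA
  eda_on_rr <- approx(eda_grid$t, eda_grid$eda, xout = rt, rule = 2)$y
  eda_line_rr <- ols_line(rt, eda_on_rr)
  eda_fit_rr <- eda_line_rr[1] + eda_line_rr[2] * rt

  out <- tibble::tibble(
    RR_Max = max(rr), RR_Min = min(rr), RR_Range = max(rr) - min(rr),
    RR_Mean = mean(rr),
    RR_Norm_Max = max(rr_n), RR_Norm_Min = min(rr_n),
    RR_Norm_Range = max(rr_n) - min(rr_n), RR_Norm_Mean = mean(rr_n),
    RR_Slope = unname(rr_line[2]), EDA_Slope = unname(eda_line[2])
  )
  out[["EDA/EDA_SurfDiff"]] <- abs_trapz(eda_grid$t, eda_grid$eda - eda_fit)
  out[["EDA/RR_SurfDiff"]] <- abs_trapz(rt, rr - eda_fit_rr)
  out[["RR/RR_SurfDiff"]] <- abs_trapz(rt, rr - rr_fit)
  out
}

#' Trailing rolling statistics of window features
#'
#' For every feature column, the mean (`_Avg`) and sample standard
#' deviation (`_Std`, n-1 denominator) over a trailing inclusive span of
#' windows: window i uses windows max(1, i-span+1)..i, so the span expands
#' until `span` windows are available and the first window gets its own
#' value with a standard deviation of 0. These act as a short-time memory
#' of the recent physiological past.
#'
#' @param feats Data frame of per-window features, rows in window order.
#' @param span Number of trailing windows, default 4.
#' @return Tibble with `2 * ncol(feats)` columns named `<f>_Avg`, `<f>_Std`.
#' @export
rolling_feature_stats <- function(feats, span = 4) {
  feats <- tibble::as_tibble(feats)
  if (nrow(feats) < 1) stop("need at least one window", call. = FALSE)
  n <- nrow(feats)
  out <- vector("list", 2L * ncol(feats))
  names(out) <- as.vector(rbind(paste0(names(feats), "_Avg"),
                                paste0(names(feats), "_Std")))
  for (j in seq_along(feats)) {
    v <- feats[[j]]
    avg <- numeric(n)
    std <- numeric(n)
    for (i in seq_len(n)) {
      w <- v[max(1L, i - span + 1L):i]
      avg[i] <- mean(w)
      std[i] <- if (length(w) > 1) sd(w) else 0
    }
    out[[2L * j - 1L]] <- avg
    out[[2L * j]] <- std
  }
  tibble::as_tibble(out)
}
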