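FREQ_FEATURES <- c("P_max", "f_Pmax")

#' Spectral features of the windowed RR signal
#'
#' Periodogram of the mean-detrended, evenly resampled RR window, with
#' one-sided power aggregated into bins of width `df` centred on
#' `seq(f_lo, f_hi, by = df)`. `P_max` is the largest bin power and
#' `f_Pmax` the frequency of that bin; ties break toward the lowest
#' frequency, so a flat (zero-power) window reports `f_Pmax = f_lo`.
#'
#' With 20 s windows the fundamental equals `f_lo` = 0.05 Hz: exactly one
#' period of the slowest component fits the window, so the lowest bins have
#' coarse resolution by construction.
#'
#' @param rr_grid Window slice of the even RR grid (tibble `t`, `rr`).
#' @param f_lo,f_hi,df Band edges and bin width (Hz); defaults 0.05, 0.5,
#'   0.05, the conventional RR band.
#' @return One-row tibble with `P_max` (s^2 per bin) and `f_Pmax` (Hz).
#' @export
freq_features <- function(rr_grid, f_lo = 0.05, f_hi = 0.5, df = 0.05) {
  n <- nrow(rr_grid)
  if (n < 4) stop("window too short for spectral analysis", call. = FALSE)
  dt <- median(diff(rr_grid$t))
  if (n * dt < 1 / f_lo - 1e-9) {
    stop(sprintf("window spans %.2f s; need >= %.2f s to resolve %g Hz",
                 n * dt, 1 / f_lo, f_lo), call. = FALSE)
  }
  x <- rr_grid$rr - mean(rr_grid$rr)
  spec <- Mod(fft(x))^2 / n^2
  k <- seq_len(floor(n / 2))          # positive frequencies, DC excluded
  freqs <- k / (n * dt)
  power <- 2 * spec[k + 1L]
  if (n %% 2 == 0) power[length(k)] <- spec[length(k) + 1L]  # Nyquist once

  centers <- seq(f_lo, f_hi, by = df)
  binpow <- vapply(centers, function(fc) {
    sum(power[abs(freqs - fc) <= df / 2 + 1e-12])
  }, numeric(1))
  ## half-open bins: a frequency on the shared edge belongs to the lower bin
  for (i in seq_along(centers)[-1]) {
    dup <- abs(freqs - (centers[i] - df / 2)) <= 1e-12
    if (any(dup)) binpow[i] <- binpow[i] - sum(power[dup])
  }
  imax <- which.max(binpow)            # first max = lowest-frequency tie-break
  tibble::tibble(P_max = binpow[imax], f_Pmax = centers[imax])
}
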