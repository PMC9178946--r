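#' Zero-phase low-pass filter
#'
#' Butterworth low-pass applied forward and backward
#' ([signal::filtfilt()]), so the output has no phase lag and window
#' timestamps stay aligned with the raw signal. The effective magnitude
#' response is the squared Butterworth response.
#'
#' @param x Numeric vector sampled on an even grid.
#' @param fs Sampling rate (Hz).
#' @param cutoff_hz Cutoff frequency (Hz), default 2.
#' @param order Butterworth order of the one-way filter, default 4.
#' @return Filtered numeric vector, same length as `x`.
#' @export
#' @examples
#' t <- seq(0, 10, by = 0.01)
#' x <- sin(2 * pi * 0.1 * t) + sin(2 * pi * 10 * t)
#' y <- lowpass_filter(x, fs = 100, cutoff_hz = 2)
lowpass_filter <- function(x, fs, cutoff_hz = 2, order = 4) {
  assert_scalar_number(fs, "fs")
  assert_scalar_number(cutoff_hz, "cutoff_hz")
  nyquist <- fs / 2
  if (cutoff_hz >= nyquist) {
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff_hz, nyquist), call. = FALSE)
  }
  min_len <- 3L * (2L * order + 1L)
  if (length(x) < min_len) {
    stop(sprintf("series too short to filter: %d samples, need >= %d",
                 length(x), min_len), call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / nyquist, type = "low")
  filtfilt_stable(bf$b, bf$a, x)
}

## direct-form-II-transposed IIR filter with explicit initial state
iir_filter <- function(b, a, x, zi) {
  nb <- length(b)
  z <- c(zi, 0)
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    for (k in seq_len(nb - 1)) {
      z[k] <- b[k + 1] * xi + z[k + 1] - a[k + 1] * yi
    }
    y[i] <- yi
  }
  y
}

## steady-state filter state for a unit step (so constants pass unscathed)
iir_zi <- function(b, a) {
  n <- length(a) - 1
  comp <- rbind(-a[-1], cbind(diag(1, n - 1), 0))  # companion matrix
  bvec <- b[-1] - a[-1] * b[1]
  solve(diag(n) - t(comp), bvec)
}

## zero-phase forward-backward filtering with odd-reflection padding and
## matched initial conditions, so edges carry no start-up transient
filtfilt_stable <- function(b, a, x) {
  n <- length(x)
  pad <- min(n - 1, max(3 * (length(a) - 1), 24))
  pre <- 2 * x[1] - x[(pad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(pre, x, post)
  zi <- iir_zi(b, a)
  y <- iir_filter(b, a, xp, zi * xp[1])
  y <- rev(iir_filter(b, a, rev(y), zi * rev(y)[1]))
  y[(pad + 1):(pad + n)]
}

#' Resample an RR tachogram onto an even grid
#'
#' The tachogram is unevenly sampled (one value per beat); regression
#' slopes, residual surfaces and spectra need an even grid. Monotone cubic
#' interpolation (Fritsch-Carlson) keeps values within the range of the
#' neighbouring beats; outside the first/last beat the edge value is held.
#'
#' @param rr_beats Data frame with columns `beat_time`, `rr`.
#' @param grid_hz Grid rate (Hz), default 4 (conventional for HRV spectra).
#' @param span Optional numeric length-2 time span to cover; defaults to
#'   first-to-last beat.
#' @param method `"monoH.FC"` (default) or `"linear"`.
#' @return Tibble with columns `t` and `rr`.
#' @export
#' @examples
#' beats <- data.frame(beat_time = cumsum(rep(0.8, 20)), rr = 0.8)
#' resample_rr(beats)
resample_rr <- function(rr_beats, grid_hz = 4, span = NULL,
                        method = c("monoH.FC", "linear")) {
  method <- match.arg(method)
  rr_beats <- tibble::as_tibble(rr_beats)
  if (nrow(rr_beats) < 2) {
    stop("need at least 2 beats to resample the tachogram", call. = FALSE)
  }
  bt <- rr_beats$beat_time
  if (is.null(span)) span <- range(bt)
  tg <- seq(span[1], span[2], by = 1 / grid_hz)
  tq <- pmin(pmax(tg, min(bt)), max(bt))  # edge hold beyond the beat span
  vals <- if (method == "linear") {
    approx(bt, rr_beats$rr, xout = tq)$y
  } else {
    ## Fritsch-Carlson tangents can overshoot marginally at turning points;
    ## clamp to the observed beat range so values stay physiological
    v <- splinefun(bt, rr_beats$rr, method = "monoH.FC")(tq)
    pmin(pmax(v, min(rr_beats$rr)), max(rr_beats$rr))
  }
  tibble::tibble(t = tg, rr = vals)
}

#' Min-max normalization parameters
#'
#' @param x Numeric vector (typically a register's whole RR signal).
#' @return List with `x_min`, `x_max`, class `norm_params`.
#' @export
norm_params <- function(x) {
  x_min <- min(x)
  x_max <- max(x)
  if (!(x_max > x_min)) {
    stop("degenerate signal: max equals min, normalization undefined",
         call. = FALSE)
  }
  structure(list(x_min = x_min, x_max = x_max), class = "norm_params")
}

#' Linear min-max normalization
#'
#' `(x - x_min) / (x_max - x_min)`: the register-wide minimum maps to 0 and
#' the maximum to 1. Parameters are normally computed once from the whole
#' register so that every window is expressed on the same subject-relative
#' scale.
#'
#' @param x Numeric vector.
#' @param params A [norm_params()] object.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' normalize_minmax(c(1, 2, 3), norm_params(c(1, 3)))
normalize_minmax <- function(x, params) {
  stopifnot(inherits(params, "norm_params"))
  (x - params$x_min) / (params$x_max - params$x_min)
}

#' Preprocess a register for windowed analysis
#'
#' Low-pass filters the EDA on its native grid, resamples the tachogram to
#' an even grid over the signals' common span, and computes the
#' register-level normalization parameters and RR_Band boundaries from the
#' gridded RR signal. The RR grid is itself low-pass filtered only when its
#' Nyquist frequency exceeds the cutoff (at the default 4 Hz grid the 2 Hz
#' cutoff equals Nyquist, and the band of interest, 0.05-0.5 Hz, is
#' unaffected either way).
#'
#' With `normalization = "whole_register"` the parameters use the whole
#' signal's extrema, as the normalised features are defined; note this
#' leaks future signal into early windows. `"causal"` instead uses running
#' extrema up to each window's end.
#'
#' @param register A [physio_register()].
#' @param cutoff_hz Low-pass cutoff (Hz), default 2.
#' @param grid_hz RR grid rate (Hz), default 4.
#' @param normalization `"whole_register"` (default) or `"causal"`.
#' @param filter_order Butterworth order, default 4.
#' @return The register with elements `eda_filt`, `rr_grid`, `norm`,
#'   `bands`, `span`, `grid_hz`, `cutoff_hz`, `normalization` added.
#' @export
preprocess_register <- function(register, cutoff_hz = 2, grid_hz = 4,
                                normalization = c("whole_register", "causal"),
                                filter_order = 4) {
  stopifnot(inherits(register, "physio_register"))
  normalization <- match.arg(normalization)
  eda_fs <- 1 / median(diff(register$eda$t))
  eda_val <- lowpass_filter(register$eda$eda, fs = eda_fs,
                            cutoff_hz = cutoff_hz, order = filter_order)
  register$eda_filt <- tibble::tibble(t = register$eda$t, eda = eda_val)

  span <- register_span(register)
  rr_grid <- resample_rr(register$rr_beats, grid_hz = grid_hz, span = span)
  if (grid_hz / 2 > cutoff_hz) {
    rr_grid$rr <- lowpass_filter(rr_grid$rr, fs = grid_hz,
                                 cutoff_hz = cutoff_hz, order = filter_order)
  }
  register$rr_grid <- rr_grid
  degenerate <- !(max(rr_grid$rr) > min(rr_grid$rr))
  if (degenerate) {
    ## a constant RR signal has no normalization or band structure; keep the
    ## register usable for windowing and let feature extraction fail loudly
    warning("constant RR signal: normalization and band boundaries undefined",
            call. = FALSE)
  }
  register$norm <- if (!degenerate) norm_params(rr_grid$rr)
  register$bands <- if (!degenerate) rr_band_boundaries(rr_grid$rr)
  register$span <- span
  register$grid_hz <- grid_hz
  register$cutoff_hz <- cutoff_hz
  register$normalization <- normalization
  register
}
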