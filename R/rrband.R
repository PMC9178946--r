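#' RR_Band boundaries from a register's RR signal
#'
#' The span between the whole signal's absolute minimum and maximum is cut
#' into three equally sized bands; the interior cut points are
#' `min + R/3` and `min + 2R/3` with `R = max - min`. Because the
#' boundaries derive from the subject's own physiology the resulting
#' feature adapts across subjects.
#'
#' @param rr Numeric vector: the whole register's (filtered, un-normalised)
#'   RR signal.
#' @return List with `rr_min`, `rr_max`, `b_low`, `b_high` (class
#'   `rr_band_boundaries`).
#' @export
#' @examples
#' rr_band_boundaries(c(0.6, 0.9, 1.2))
rr_band_boundaries <- function(rr) {
  rr_min <- min(rr)
  rr_max <- max(rr)
  if (!(rr_max > rr_min)) {
    stop("degenerate signal: constant RR, band boundaries undefined",
         call. = FALSE)
  }
  r <- rr_max - rr_min
  structure(
    list(rr_min = rr_min, rr_max = rr_max,
         b_low = rr_min + r / 3, b_high = rr_min + 2 * r / 3),
    class = "rr_band_boundaries"
  )
}

#' Discretize window-mean RR into one of three bands
#'
#' Band 1 is the relaxation band (top third of the span: longest intervals,
#' slowest heart), band 2 the basal/rest band and band 3 the stress band
#' (shortest intervals). Intervals are `[min, b_low)`, `[b_low, b_high)`
#' and `[b_high, max]`, so a value landing exactly on a boundary goes to
#' the calmer band; values outside the register span clamp to the nearest
#' band.
#'
#' @param rr_mean Numeric vector of window-mean RR values (s).
#' @param bounds An [rr_band_boundaries()] object.
#' @return Integer vector of bands in `{1, 2, 3}`.
#' @export
#' @examples
#' b <- rr_band_boundaries(c(0.6, 1.2))
#' assign_rr_band(c(1.1, 0.9, 0.7), b)
assign_rr_band <- function(rr_mean, bounds) {
  stopifnot(inherits(bounds, "rr_band_boundaries"))
  ifelse(rr_mean >= bounds$b_high, 1L,
         ifelse(rr_mean >= bounds$b_low, 2L, 3L))
}
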