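POINCARE_FEATURES <- c("SD1c", "SD2c", "SD1b", "SD1e", "SD1d",
                       "n_e", "n_d", "Ce", "Cd")

#' Lag-1 Poincare plot of an RR sequence
#'
#' Each beat interval is plotted against its successor:
#' `x = {RR_1..RR_(n-1)}`, `y = {RR_2..RR_n}`. The cloud of a healthy
#' recording is elliptical around the identity line; its geometry carries
#' the short- and long-term variability descriptors.
#'
#' @param rr Numeric vector of beat intervals (s), length >= 2.
#' @return A `poincare_plot`: list with `points` (tibble `x`, `y`),
#'   centroid `x_c`, `y_c`, and the centroid-referenced distances `d1`
#'   (across the identity line) and `d2` (along it).
#' @export
#' @examples
#' poincare_plot(c(0.8, 0.9, 1.0, 1.1))
poincare_plot <- function(rr) {
  rr <- as.numeric(rr)
  n <- length(rr)
  if (n < 2) stop("need at least 2 beats for a Poincare plot", call. = FALSE)
  x <- rr[-n]
  y <- rr[-1]
  x_c <- mean(x)
  y_c <- mean(y)
  structure(
    list(points = tibble::tibble(x = x, y = y), x_c = x_c, y_c = y_c,
         d1 = abs((x - x_c) - (y - y_c)) / sqrt(2),
         d2 = abs((x - x_c) + (y - y_c)) / sqrt(2)),
    class = "poincare_plot"
  )
}

#' Poincare descriptors of an RR sequence
#'
#' Nine descriptors of the lag-1 plot. `SD1c`/`SD2c` are the RMS
#' centroid-referenced distances across/along the identity line (semi-minor
#' and semi-major ellipse axes). `SD1b` measures short-term variability
#' about the bisector `x = y` itself, `sqrt(sum((x-y)^2) / (2n))` with `n`
#' the number of plotted points, and decomposes exactly into an
#' acceleration and a deceleration part: `SD1e` uses only points above the
#' bisector (`y > x`, decelerating heart) and `SD1d` points below, both
#' normalised by the same `2n`, so `SD1e^2 + SD1d^2 = SD1b^2` and the
#' contributions `Ce = SD1e^2/SD1b^2`, `Cd = SD1d^2/SD1b^2` sum to one.
#' `n_e`/`n_d` count the points on either side; points exactly on the
#' bisector contribute zero and are counted in neither.
#'
#' For a constant sequence all points coincide on the bisector, `SD1b = 0`
#' and `Ce`/`Cd` are undefined (`NA`).
#'
#' @param rr Numeric vector of beat intervals, or a [poincare_plot()].
#' @return One-row tibble with columns `SD1c`, `SD2c`, `SD1b`, `SD1e`,
#'   `SD1d`, `n_e`, `n_d`, `Ce`, `Cd`.
#' @export
#' @examples
#' poincare_descriptors(c(0.8, 1.0, 0.8, 1.0, 0.8))
poincare_descriptors <- function(rr) {
  plot <- if (inherits(rr, "poincare_plot")) rr else poincare_plot(rr)
  x <- plot$points$x
  y <- plot$points$y
  n <- length(x)
  sq <- (x - y)^2
  above <- y > x
  below <- y < x
  sd1b2 <- sum(sq) / (2 * n)
  sd1e2 <- sum(sq[above]) / (2 * n)
  sd1d2 <- sum(sq[below]) / (2 * n)
  tibble::tibble(
    SD1c = sqrt(mean(plot$d1^2)),
    SD2c = sqrt(mean(plot$d2^2)),
    SD1b = sqrt(sd1b2),
    SD1e = sqrt(sd1e2),
    SD1d = sqrt(sd1d2),
    n_e = sum(above),
    n_d = sum(below),
    Ce = if (sd1b2 > 0) sd1e2 / sd1b2 else NA_real_,
    Cd = if (sd1b2 > 0) sd1d2 / sd1b2 else NA_real_
  )
}

#' Plot a Poincare scatter with its centroid
#'
#' @param rr Numeric vector of beat intervals or a [poincare_plot()].
#' @return A ggplot.
#' @export
plot_poincare <- function(rr) {
  plot <- if (inherits(rr, "poincare_plot")) rr else poincare_plot(rr)
  ggplot2::ggplot(plot$points, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::annotate("point", x = plot$x_c, y = plot$y_c, colour = "red",
                      size = 3, shape = 4) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(RR[i] ~ "(s)"), y = expression(RR[i + 1] ~ "(s)"))
}
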