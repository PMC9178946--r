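#' Friedman omnibus test over paired metric blocks
#'
#' Rank-based test of the null that all algorithms perform equivalently,
#' computed from a blocks-by-algorithms matrix of paired measurements (here
#' the runs x folds cross-validation metrics). Uses average ranks for ties
#' and the chi-square approximation ([stats::friedman.test()]); the
#' conventional significance level in this pipeline is 0.05.
#'
#' @param metrics Numeric matrix, blocks in rows and algorithms in columns,
#'   or an `rresp_cv` object (blocks are then the run-fold pairs).
#' @param metric Metric column when `metrics` is an `rresp_cv`; default
#'   `"accuracy"`.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' m <- cbind(a = c(3, 3, 3), b = c(2, 2, 2), c = c(1, 1, 1))
#' friedman_test(m)
friedman_test <- function(metrics, metric = "accuracy") {
  if (inherits(metrics, "rresp_cv")) {
    metrics <- cv_metric_matrix(metrics, metric)
  }
  metrics <- as.matrix(metrics)
  if (ncol(metrics) < 2) stop("need at least 2 algorithms", call. = FALSE)
  if (nrow(metrics) < 2) stop("need at least 2 blocks", call. = FALSE)
  ft <- stats::friedman.test(metrics)
  stat <- unname(ft$statistic)
  p <- ft$p.value
  if (is.nan(stat)) {
    ## complete ties in every block: no evidence against equivalence
    stat <- 0
    p <- 1
  }
  tibble::tibble(statistic = stat, df = unname(ft$parameter), p_value = p)
}

## blocks-by-algorithms matrix of one metric, blocks ordered by (run, fold)
cv_metric_matrix <- function(cv, metric = "accuracy") {
  stopifnot(inherits(cv, "rresp_cv"))
  wide <- cv$folds_tbl |>
    dplyr::select("algorithm", "run", "fold", dplyr::all_of(metric)) |>
    tidyr::pivot_wider(names_from = "algorithm",
                       values_from = dplyr::all_of(metric)) |>
    dplyr::arrange(.data$run, .data$fold)
  as.matrix(wide[, -(1:2)])
}

#' Bayesian correlated t-test on paired cross-validation differences
#'
#' Posterior inference on the mean metric difference `mu` between two
#' classifiers evaluated on the same cross-validation folds. Fold overlap
#' makes the `n` measurements correlated, which the correlated variance
#' correction handles: the posterior of `mu` is a Student-t with `n - 1`
#' degrees of freedom, location `mean(x)` and squared scale
#' `(1/n + rho/(1 - rho)) * var(x)`, where `rho` is the fold-correlation
#' heuristic `n_test/n_total = 1/folds`. The posterior mass is split over
#' `(-Inf, -rope)`, `[-rope, +rope]` and `(rope, Inf)`; the region of
#' practical equivalence (ROPE) treats differences smaller than `rope`
#' (default 0.01 on the accuracy scale) as no meaningful difference. The
#' verdict is the region holding the most mass.
#'
#' A zero-variance difference vector collapses the posterior to a point
#' mass at `mean(x)`; a point mass exactly on a ROPE edge counts as inside
#' and the result is flagged with a `boundary` attribute.
#'
#' @param x Numeric vector of per-fold metric differences (row minus
#'   column), length `runs * folds`.
#' @param rope ROPE half-width, default 0.01.
#' @param rho Fold-correlation parameter in (0, 1), default 0.1.
#' @return An `rresp_bc` object (list with `mu_hat`, `scale`, `dof`,
#'   `rho`, `rope`, `p_left`, `p_rope`, `p_right`, `verdict`).
#' @export
#' @examples
#' bc_ttest(rnorm(100, 0.02, 0.01))
bc_ttest <- function(x, rope = 0.01, rho = 0.1) {
  n <- length(x)
  if (n < 2) stop("need at least 2 paired differences", call. = FALSE)
  if (rho <= 0 || rho >= 1) stop("rho must be in (0, 1)", call. = FALSE)
  mu_hat <- mean(x)
  s2 <- var(x)
  dof <- n - 1
  scale <- sqrt((1 / n + rho / (1 - rho)) * s2)
  boundary <- FALSE
  if (scale == 0) {
    p_left <- as.numeric(mu_hat < -rope)
    p_right <- as.numeric(mu_hat > rope)
    p_rope <- 1 - p_left - p_right      # edges count as inside the ROPE
    boundary <- abs(abs(mu_hat) - rope) < .Machine$double.eps * 4
  } else {
    p_left <- pt((-rope - mu_hat) / scale, dof)
    p_right <- 1 - pt((rope - mu_hat) / scale, dof)
    p_rope <- 1 - p_left - p_right
  }
  probs <- c(left = p_left, rope = p_rope, right = p_right)
  verdict <- c("column_better", "equivalent",
               "row_better")[which.max(probs)]
  structure(
    list(x = x, n = n, mu_hat = mu_hat, scale = scale, dof = dof, rho = rho,
         rope = rope, p_left = unname(p_left), p_rope = unname(p_rope),
         p_right = unname(p_right), verdict = verdict, boundary = boundary),
    class = "rresp_bc"
  )
}

#' @export
print.rresp_bc <- function(x, ...) {
  cat(sprintf("<rresp_bc> mu_hat = %.4f, scale = %.4f, dof = %d, rope = +/-%g\n",
              x$mu_hat, x$scale, x$dof, x$rope))
  cat(sprintf("  P(left) = %.3f  P(rope) = %.3f  P(right) = %.3f -> %s\n",
              x$p_left, x$p_rope, x$p_right, x$verdict))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rresp_bc <- function(x, ...) {
  tibble::tibble(mu_hat = x$mu_hat, scale = x$scale, dof = x$dof,
                 rho = x$rho, rope = x$rope, p_left = x$p_left,
                 p_rope = x$p_rope, p_right = x$p_right, verdict = x$verdict)
}

#' Pairwise comparison matrix of a cross-validated roster
#'
#' For every ordered pair of algorithms, the per-fold differences of the
#' chosen metric (row minus column, runs pooled into one vector) feed a
#' [bc_ttest()]. Each cell reports the probability of the winning region
#' and the verdict; swapping row and column swaps left and right masses, so
#' the matrix is antisymmetric by construction.
#'
#' @param cv An `rresp_cv` with at least 2 algorithms (paired folds).
#' @param metric `"accuracy"` (default), `"f1"` or `"auc"`.
#' @param rope,rho Passed to [bc_ttest()]; `rho` defaults to `1/folds`.
#' @return An `rresp_comparison` object; `tidy()` gives the cell table,
#'   [autoplot()] the matrix rendering.
#' @export
build_comparison_matrix <- function(cv, metric = "accuracy", rope = 0.01,
                                    rho = NULL) {
  stopifnot(inherits(cv, "rresp_cv"))
  mm <- cv_metric_matrix(cv, metric)
  algs <- colnames(mm)
  if (length(algs) < 2) stop("need at least 2 algorithms", call. = FALSE)
  if (is.null(rho)) rho <- 1 / cv$folds
  cells <- list()
  tests <- list()
  for (i in seq_along(algs)) {
    for (j in seq_along(algs)) {
      if (i == j) next
      bc <- bc_ttest(mm[, i] - mm[, j], rope = rope, rho = rho)
      tests[[paste(algs[i], algs[j], sep = " vs ")]] <- bc
      win_p <- max(bc$p_left, bc$p_rope, bc$p_right)
      cells[[length(cells) + 1L]] <- tibble::tibble(
        row = algs[i], column = algs[j], mu_hat = bc$mu_hat,
        p_left = bc$p_left, p_rope = bc$p_rope, p_right = bc$p_right,
        probability = win_p, verdict = bc$verdict
      )
    }
  }
  structure(
    list(cells = dplyr::bind_rows(cells), tests = tests, algorithms = algs,
         metric = metric, rope = rope, rho = rho),
    class = "rresp_comparison"
  )
}

#' @export
print.rresp_comparison <- function(x, ...) {
  cat(sprintf("<rresp_comparison> %s, rope = +/-%g, rho = %g\n",
              x$metric, x$rope, x$rho))
  print(x$cells)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rresp_comparison <- function(x, ...) x$cells

#' Render a comparison matrix
#'
#' Green cells: the row algorithm is probably better than the column one;
#' red: probably worse; grey: the region of practical equivalence holds the
#' most mass. Each cell prints the probability of its winning region.
#'
#' @param object An `rresp_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.rresp_comparison <- function(object, ...) {
  cells <- object$cells
  cells$row <- factor(cells$row, levels = object$algorithms)
  cells$column <- factor(cells$column, levels = object$algorithms)
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$column, y = .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$verdict,
                                    alpha = .data$probability),
                       colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$probability)),
                       size = 3) +
    ggplot2::scale_fill_manual(
      values = c(row_better = "#31a354", column_better = "#de2d26",
                 equivalent = "grey70"),
      name = NULL
    ) +
    ggplot2::scale_alpha(range = c(0.35, 1), guide = "none") +
    ggplot2::scale_y_discrete(limits = rev(object$algorithms)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Pairwise Bayesian comparison (%s)",
                                  object$metric))
}
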