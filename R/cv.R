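## grouped fold assignment: whole groups (e.g. subjects) are dealt to
## folds round-robin after shuffling, so no group straddles a fold boundary
grouped_folds <- function(groups, folds) {
  ids <- unique(groups)
  if (length(ids) < folds) {
    stop(sprintf("only %d groups for %d folds", length(ids), folds),
         call. = FALSE)
  }
  fold_of_id <- rep_len(seq_len(folds), length(ids))
  names(fold_of_id) <- sample(ids)
  unname(fold_of_id[as.character(groups)])
}

## stratified fold assignment: within each class, shuffled indices are
## dealt to folds round-robin, so every class appears in every fold
stratified_folds <- function(y, folds) {
  assign <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    if (length(idx) < folds) {
      stop(sprintf("class '%s' has %d instances; need at least %d (one per fold)",
                   lv, length(idx), folds), call. = FALSE)
    }
    idx <- sample(idx)
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

## weighted one-vs-rest AUC, weights = class prevalence in the test fold
weighted_auc <- function(y, prob) {
  lv <- levels(y)
  prev <- as.numeric(table(y)[lv])
  aucs <- rep(NA_real_, length(lv))
  for (i in seq_along(lv)) {
    resp <- as.integer(y == lv[i])
    if (length(unique(resp)) < 2) next
    aucs[i] <- as.numeric(pROC::auc(
      response = resp, predictor = prob[, lv[i]],
      levels = c(0, 1), direction = "<", quiet = TRUE
    ))
  }
  ok <- !is.na(aucs) & prev > 0
  sum(aucs[ok] * prev[ok]) / sum(prev[ok])
}

## weighted F1 over classes present in the test fold
weighted_f1 <- function(y, pred) {
  lv <- levels(y)
  f1 <- numeric(length(lv))
  prev <- as.numeric(table(y)[lv])
  for (i in seq_along(lv)) {
    tp <- sum(pred == lv[i] & y == lv[i])
    fp <- sum(pred == lv[i] & y != lv[i])
    fn <- sum(pred != lv[i] & y == lv[i])
    f1[i] <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  ok <- prev > 0
  sum(f1[ok] * prev[ok]) / sum(prev[ok])
}

#' Repeated stratified cross-validation of a classifier roster
#'
#' Runs `runs` repetitions of stratified `folds`-fold cross-validation.
#' The fold partitions are drawn once per run from the seed and reused
#' across all algorithms, so per-fold metrics are paired and downstream
#' comparisons ([build_comparison_matrix()], [friedman_test()]) are valid.
#' Per fold, accuracy, prevalence-weighted F1 and prevalence-weighted
#' one-vs-rest AUC are recorded, along with the fold confusion matrix.
#' The majority-class baseline accuracy is reported alongside.
#'
#' @param table Feature table with a `label` factor column.
#' @param algorithms List of algorithm specs from [rresp_algorithms()].
#' @param runs,folds Repetitions and folds; default 10 x 10.
#' @param seed Integer seed driving partitions and every stochastic
#'   learner.
#' @param features Feature columns to use; default [feature_columns()].
#' @param groups Optional name of a grouping column (e.g. `"subject_id"`):
#'   folds are then assembled from whole groups, so temporally overlapping
#'   windows of one subject never land on both sides of a fold boundary and
#'   the measured accuracy is between-subject generalization. The default
#'   (`NULL`) stratifies individual instances by class, the conventional
#'   pooled-window design.
#' @return An `rresp_cv` object; see [tidy()] for per-fold metrics and
#'   [glance()] for per-algorithm aggregates.
#' @export
#' @examples
#' tab <- synth_cohort_table(2, synth_schedule(c(Basal = 100, Stress = 100,
#'                                               Relax = 100)), seed = 1)
#' cv <- run_cv(tab, rresp_algorithms(c("DT", "RF")), runs = 2, seed = 7)
#' glance(cv)
run_cv <- function(table, algorithms = rresp_algorithms(), runs = 10,
                   folds = 10, seed = 1, features = NULL, groups = NULL) {
  stopifnot("label" %in% names(table))
  y <- table$label
  if (!is.factor(y)) y <- factor(y)
  y <- droplevels(y)
  if (anyNA(y)) stop("training tables must have no missing labels", call. = FALSE)
  if (is.null(features)) features <- feature_columns(table)
  x <- as.data.frame(table[features])
  names(x) <- make.names(names(x), unique = TRUE)  # syntactic for formulas
  lv <- levels(y)
  k <- length(lv)

  ## partitions, shared by all algorithms
  partitions <- purrr::map(seq_len(runs), function(r) {
    set.seed(derive_seed(seed, 101, r))
    if (is.null(groups)) {
      stratified_folds(y, folds)
    } else {
      grouped_folds(table[[groups]], folds)
    }
  })

  fold_rows <- list()
  confusion <- list()
  for (ai in seq_along(algorithms)) {
    spec <- algorithms[[ai]]
    conf_runs <- array(0, dim = c(k, k, runs), dimnames = list(lv, lv, NULL))
    for (r in seq_len(runs)) {
      fold_of <- partitions[[r]]
      for (f in seq_len(folds)) {
        test <- fold_of == f
        set.seed(derive_seed(seed, 202, ai, r, f))
        model <- spec$fit(x[!test, , drop = FALSE], y[!test])
        prob <- spec$predict(model, x[test, , drop = FALSE])
        prob <- as.matrix(prob)[, lv, drop = FALSE]
        pred <- factor(lv[max.col(prob, ties.method = "first")], levels = lv)
        yt <- y[test]
        cm <- table(true = yt, predicted = pred)
        conf_runs[, , r] <- conf_runs[, , r] + as.matrix(cm)
        fold_rows[[length(fold_rows) + 1L]] <- tibble::tibble(
          algorithm = spec$id, run = r, fold = f,
          accuracy = mean(pred == yt),
          f1 = weighted_f1(yt, pred),
          auc = weighted_auc(yt, prob)
        )
      }
    }
    confusion[[spec$id]] <- apply(conf_runs, c(1, 2), mean)
  }

  fold_tbl <- dplyr::bind_rows(fold_rows)
  fold_tbl$algorithm <- factor(fold_tbl$algorithm,
                               levels = purrr::map_chr(algorithms, "id"))
  structure(
    list(folds_tbl = fold_tbl, confusion = confusion, levels = lv,
         runs = runs, folds = folds, seed = seed,
         n_instances = length(y),
         baseline = max(table(y)) / length(y),
         features = features),
    class = "rresp_cv"
  )
}

#' @export
print.rresp_cv <- function(x, ...) {
  cat(sprintf("<rresp_cv> %d-run %d-fold CV, %d instances, %d features\n",
              x$runs, x$folds, x$n_instances, length(x$features)))
  cat(sprintf("  majority-class baseline accuracy: %.3f\n", x$baseline))
  print(glance(x))
  invisible(x)
}

#' Per-fold metrics of a cross-validation
#'
#' @param x An `rresp_cv` object.
#' @param ... Unused.
#' @return Tibble with one row per (algorithm, run, fold): `accuracy`,
#'   `f1`, `auc`.
#' @exportS3Method generics::tidy
tidy.rresp_cv <- function(x, ...) x$folds_tbl

#' Per-algorithm aggregate metrics
#'
#' @param x An `rresp_cv` object.
#' @param ... Unused.
#' @return Tibble with mean and sd of each metric per algorithm.
#' @exportS3Method generics::glance
glance.rresp_cv <- function(x, ...) {
  x$folds_tbl |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::summarise(dplyr::across(c("accuracy", "f1", "auc"),
                                   list(mean = mean, sd = sd)),
                     .groups = "drop")
}

#' Mean confusion matrix of an algorithm
#'
#' Rows are the true class, columns the predicted class; entries are mean
#' counts per run (each run's folds partition the data, so entries sum to
#' the instance count).
#'
#' @param cv An `rresp_cv` object.
#' @param algorithm Algorithm id; default the first evaluated.
#' @return A square numeric matrix.
#' @export
confusion_matrix <- function(cv, algorithm = names(cv$confusion)[1]) {
  stopifnot(inherits(cv, "rresp_cv"))
  if (!algorithm %in% names(cv$confusion)) {
    stop("no such algorithm in this cv: ", algorithm, call. = FALSE)
  }
  cv$confusion[[algorithm]]
}
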