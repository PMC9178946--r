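## 50 base feature names + RR_Band = 51 columns before selection
all_feature_names <- function() {
  c(TIME_FEATURES,
    as.vector(rbind(paste0(TIME_FEATURES, "_Avg"), paste0(TIME_FEATURES, "_Std"))),
    FREQ_FEATURES, POINCARE_FEATURES, "RR_Band")
}

#' Extract the full feature set from a window set
#'
#' Per window: the 13 time-domain features, their 26 trailing rolling
#' statistics, the 2 spectral features, the 9 Poincare descriptors (from
#' the raw beat intervals inside the window) and the RR_Band code — 51
#' features in total. Rolling statistics run over all windows in order,
#' labelled or not, so the short-time memory is not interrupted by
#' unlabelled stretches.
#'
#' Normalised features use the register-level parameters attached to the
#' window set; under causal normalization the running extrema of the RR
#' grid up to each window's end are used instead.
#'
#' @param windows A `window_set` from [segment_windows()] (after
#'   [assign_labels()] if labels are wanted).
#' @param rolling_span Trailing window count for `_Avg`/`_Std`, default 4.
#' @param f_lo,f_hi,df Spectral band and bin width passed to
#'   [freq_features()].
#' @return Tibble with columns `subject_id`, `window`, `t_start`, the 51
#'   features and `label`; the feature names are stored in the
#'   `feature_cols` attribute (see [feature_columns()]).
#' @export
extract_features <- function(windows, rolling_span = 4,
                             f_lo = 0.05, f_hi = 0.5, df = 0.05) {
  stopifnot(inherits(windows, "window_set"))
  norm <- attr(windows, "norm")
  bands <- attr(windows, "bands")
  causal <- identical(attr(windows, "normalization"), "causal")
  rr_full <- attr(windows, "rr_grid_full")

  tf <- purrr::map(seq_len(nrow(windows)), function(i) {
    np <- norm
    if (causal) {
      seen <- rr_full$rr[rr_full$t < windows$t_end[i] - 1e-9]
      np <- norm_params(seen)
    }
    time_features(windows$rr_grid[[i]], windows$eda_grid[[i]], np)
  })
  tf <- dplyr::bind_rows(tf)
  roll <- rolling_feature_stats(tf, span = rolling_span)
  fr <- dplyr::bind_rows(purrr::map(windows$rr_grid, freq_features,
                                    f_lo = f_lo, f_hi = f_hi, df = df))
  pc <- dplyr::bind_rows(purrr::map(windows$rr_beats,
                                    function(b) poincare_descriptors(b$rr)))
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = attr(windows, "subject_id"),
                   window = windows$window, t_start = windows$t_start),
    tf, roll, fr, pc
  )
  out$RR_Band <- assign_rr_band(out$RR_Mean, bands)
  out$label <- windows$label
  attr(out, "feature_cols") <- all_feature_names()
  out
}

#' Feature columns of a feature table
#'
#' @param table A feature table (from [extract_features()] or
#'   [build_feature_table()]) or any data frame; falls back to every
#'   numeric column that is not metadata (`subject_id`, `window`,
#'   `t_start`) or `label`.
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(table) {
  fc <- attr(table, "feature_cols")
  if (!is.null(fc)) return(intersect(fc, names(table)))
  setdiff(names(table)[vapply(table, is.numeric, logical(1))],
          c("window", "t_start", "t_end"))
}

#' Build a labelled feature table from a register
#'
#' Chains the whole pipeline: preprocessing, windowing, label assignment
#' from the register's annotations, feature extraction, and removal of
#' unlabelled windows and of windows with undefined descriptors (e.g. a
#' constant-RR window, whose Poincare contributions are undefined).
#'
#' @param register A [physio_register()] with annotations.
#' @param window_s,overlap_s Windowing parameters, see [segment_windows()].
#' @param min_coverage Label coverage threshold, see [assign_labels()].
#' @param rolling_span Trailing span for rolling statistics.
#' @param ... Passed to [preprocess_register()] (e.g. `cutoff_hz`,
#'   `grid_hz`, `normalization`).
#' @return Tibble of labelled instances: metadata, 51 feature columns and
#'   `label`.
#' @export
#' @examples
#' reg <- generate_register(synth_schedule(), seed = 7)
#' tab <- build_feature_table(reg)
#' dplyr::count(tab, label)
build_feature_table <- function(register, window_s = 20, overlap_s = 5,
                                min_coverage = 0.5, rolling_span = 4, ...) {
  stopifnot(inherits(register, "physio_register"))
  register <- preprocess_register(register, ...)
  win <- segment_windows(register, window_s = window_s, overlap_s = overlap_s)
  win <- assign_labels(win, register$annotations, min_coverage = min_coverage)
  tab <- extract_features(win, rolling_span = rolling_span)
  fc <- attr(tab, "feature_cols")
  keep <- !is.na(tab$label)
  complete <- stats::complete.cases(tab[fc])
  if (any(keep & !complete)) {
    warning(sprintf("dropping %d window(s) with undefined feature values",
                    sum(keep & !complete)), call. = FALSE)
  }
  out <- tab[keep & complete, , drop = FALSE]
  out$label <- droplevels(out$label)
  out$label <- factor(as.character(out$label), levels = RRESP_LEVELS)
  attr(out, "feature_cols") <- fc
  out
}

#' Write a feature table to delimited text
#'
#' Columns are named exactly as the features (including the `/` forms) plus
#' `label`; metadata columns are kept in front.
#'
#' @param table Feature table.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_feature_table <- function(table, file) {
  readr::write_csv(table, file)
  invisible(file)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param file CSV path.
#' @return Tibble with `label` as a factor and the `feature_cols`
#'   attribute restored for known columns.
#' @export
read_feature_table <- function(file) {
  tab <- readr::read_csv(file, show_col_types = FALSE)
  if ("label" %in% names(tab)) {
    tab$label <- factor(tab$label, levels = RRESP_LEVELS)
  }
  attr(tab, "feature_cols") <- intersect(all_feature_names(), names(tab))
  tab
}
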