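#' Slice a register into overlapping analysis windows
#'
#' Windows are 20 s long by default and slide with a 5 s overlap (15 s
#' stride), half-open `[t_start, t_end)` on a time axis anchored at the
#' first instant both signals exist. Trailing partial windows are
#' discarded; windows holding fewer than 2 beats are dropped with a
#' warning.
#'
#' @param register A preprocessed [physio_register()] (preprocessing is run
#'   with defaults if missing).
#' @param window_s Window length (s), default 20.
#' @param overlap_s Overlap between consecutive windows (s), default 5.
#' @return A `window_set`: a tibble with one row per window (`window`,
#'   `t_start`, `t_end`, `n_beats`, `label` and list-columns `rr_grid`,
#'   `eda_grid`, `rr_beats`), carrying the register's normalization
#'   parameters and band boundaries as attributes.
#' @export
#' @examples
#' reg <- generate_register(synth_schedule(c(Basal = 60)), seed = 1)
#' segment_windows(reg)
segment_windows <- function(register, window_s = 20, overlap_s = 5) {
  stopifnot(inherits(register, "physio_register"))
  if (overlap_s >= window_s) {
    stop("overlap must be smaller than the window length", call. = FALSE)
  }
  if (is.null(register$rr_grid)) register <- preprocess_register(register)
  span <- register$span
  total <- span[2] - span[1]
  if (total < window_s) {
    stop(sprintf("register duration (%.1f s) shorter than one window (%g s)",
                 total, window_s), call. = FALSE)
  }
  stride <- window_s - overlap_s
  n_win <- floor((total - window_s) / stride) + 1
  starts <- span[1] + (seq_len(n_win) - 1) * stride

  eps <- 1e-9
  rows <- purrr::map(starts, function(s) {
    e <- s + window_s
    rg <- register$rr_grid[register$rr_grid$t >= s - eps &
                             register$rr_grid$t < e - eps, ]
    eg <- register$eda_filt[register$eda_filt$t >= s - eps &
                              register$eda_filt$t < e - eps, ]
    rb <- register$rr_beats[register$rr_beats$beat_time >= s - eps &
                              register$rr_beats$beat_time < e - eps, ]
    tibble::tibble(t_start = s, t_end = e, n_beats = nrow(rb),
                   rr_grid = list(rg), eda_grid = list(eg),
                   rr_beats = list(rb))
  })
  win <- dplyr::bind_rows(rows)
  few <- win$n_beats < 2
  if (any(few)) {
    warning(sprintf("dropping %d window(s) with fewer than 2 beats", sum(few)),
            call. = FALSE)
    win <- win[!few, ]
  }
  win <- dplyr::mutate(win, window = dplyr::row_number(),
                       label = factor(NA_character_, levels = RRESP_LEVELS),
                       .before = 1)
  structure(
    win,
    class = c("window_set", class(tibble::tibble())),
    subject_id = register$subject_id,
    norm = register$norm,
    bands = register$bands,
    rr_grid_full = register$rr_grid,
    normalization = register$normalization %||% "whole_register",
    window_s = window_s,
    stride = stride
  )
}

#' Attach ground-truth labels to windows
#'
#' A window is labelled iff a single annotation interval covers at least
#' `min_coverage` of it; when two annotations tie for maximal coverage the
#' window stays unlabelled, as do windows no annotation covers enough.
#'
#' @param windows A `window_set` from [segment_windows()].
#' @param annotations Annotation data frame (`t_start`, `t_end`, `label`);
#'   `NULL` leaves all windows unlabelled.
#' @param min_coverage Minimum covered fraction of the window, default 0.5.
#' @return The `window_set` with its `label` column filled in.
#' @export
assign_labels <- function(windows, annotations, min_coverage = 0.5) {
  stopifnot(inherits(windows, "window_set"))
  if (is.null(annotations) || nrow(annotations) == 0) return(windows)
  ann <- validate_annotations(annotations)
  wlen <- attr(windows, "window_s")
  labs <- purrr::map_chr(seq_len(nrow(windows)), function(i) {
    s <- windows$t_start[i]
    e <- windows$t_end[i]
    cov <- pmax(0, pmin(e, ann$t_end) - pmax(s, ann$t_start)) / wlen
    best <- max(cov)
    if (best < min_coverage) return(NA_character_)
    if (sum(abs(cov - best) < 1e-9) > 1L) return(NA_character_)  # tie
    as.character(ann$label[which.max(cov)])
  })
  windows$label <- factor(labs, levels = RRESP_LEVELS)
  windows
}
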