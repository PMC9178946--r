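#' Construct a physiological register
#'
#' A register bundles one subject's electrodermal activity (EDA) series, RR
#' tachogram and optional mental-state annotations. Times are in seconds on a
#' common clock; EDA is in microsiemens, RR intervals in seconds.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param eda Data frame with columns `t` (s, strictly increasing) and
#'   `eda` (uS).
#' @param rr_beats Data frame with columns `beat_time` (s, strictly
#'   increasing) and `rr` (s, strictly positive): each row is one heartbeat
#'   and the interval that ended at it.
#' @param annotations Optional data frame with columns `t_start`, `t_end`
#'   (s) and `label` (one of [rresp_classes()]); intervals must not overlap.
#' @param meta Optional list of free-form provenance.
#'
#' @return An object of class `physio_register`.
#' @export
#' @examples
#' reg <- physio_register(
#'   "s1",
#'   eda = data.frame(t = seq(0, 10, 0.125), eda = 5),
#'   rr_beats = data.frame(beat_time = seq(0.8, 10, 0.8), rr = 0.8)
#' )
#' reg
physio_register <- function(subject_id, eda, rr_beats, annotations = NULL,
                            meta = list()) {
  eda <- tibble::as_tibble(eda)
  rr_beats <- tibble::as_tibble(rr_beats)
  stopifnot(all(c("t", "eda") %in% names(eda)),
            all(c("beat_time", "rr") %in% names(rr_beats)))
  if (any(diff(eda$t) <= 0)) {
    stop("EDA timestamps must be strictly increasing", call. = FALSE)
  }
  if (any(rr_beats$rr <= 0)) {
    stop("RR intervals must be strictly positive", call. = FALSE)
  }
  if (any(diff(rr_beats$beat_time) <= 0)) {
    stop("beat times must be strictly increasing", call. = FALSE)
  }
  if (!is.null(annotations)) {
    annotations <- validate_annotations(annotations)
  }
  structure(
    list(subject_id = as.character(subject_id), eda = eda,
         rr_beats = rr_beats, annotations = annotations, meta = meta),
    class = "physio_register"
  )
}

validate_annotations <- function(annotations) {
  annotations <- tibble::as_tibble(annotations)
  stopifnot(all(c("t_start", "t_end", "label") %in% names(annotations)))
  if (any(annotations$t_end <= annotations$t_start)) {
    stop("annotation intervals must have t_end > t_start", call. = FALSE)
  }
  bad <- !annotations$label %in% RRESP_LEVELS
  if (any(bad)) {
    stop("unknown annotation labels: ",
         paste(unique(annotations$label[bad]), collapse = ", "), call. = FALSE)
  }
  ann <- annotations[order(annotations$t_start), ]
  if (nrow(ann) > 1 &&
      any(ann$t_start[-1] < ann$t_end[-nrow(ann)] - 1e-9)) {
    stop("annotation intervals overlap", call. = FALSE)
  }
  ann$label <- factor(ann$label, levels = RRESP_LEVELS)
  ann
}

#' Read a register from delimited text files
#'
#' One CSV/TSV file per signal: the EDA file has columns `t,eda`, the RR
#' file `beat_time,rr` and the optional annotations file
#' `t_start,t_end,label`. A header row is required; times are seconds with a
#' `.` decimal point.
#'
#' @param eda_file,rr_file,annotations_file File paths; `annotations_file`
#'   may be `NULL`.
#' @param subject_id Subject identifier; defaults to the EDA file stem.
#' @return A [physio_register()].
#' @export
read_register <- function(eda_file, rr_file, annotations_file = NULL,
                          subject_id = NULL) {
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]+$", "", basename(eda_file))
  }
  eda <- readr::read_delim(eda_file, show_col_types = FALSE, trim_ws = TRUE)
  rr <- readr::read_delim(rr_file, show_col_types = FALSE, trim_ws = TRUE)
  ann <- if (!is.null(annotations_file)) {
    readr::read_delim(annotations_file, show_col_types = FALSE, trim_ws = TRUE)
  }
  physio_register(subject_id, eda = eda, rr_beats = rr, annotations = ann,
                  meta = list(eda_file = eda_file, rr_file = rr_file))
}

#' Write a register to delimited text files
#'
#' Inverse of [read_register()]: writes `<stem>_eda.csv`, `<stem>_rr.csv`
#' and, when annotations are present, `<stem>_annotations.csv`.
#'
#' @param register A [physio_register()].
#' @param dir Output directory (created if missing).
#' @param stem File-name stem; defaults to the subject id.
#' @return Invisibly, the paths written.
#' @export
write_register <- function(register, dir, stem = register$subject_id) {
  stopifnot(inherits(register, "physio_register"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    eda = file.path(dir, paste0(stem, "_eda.csv")),
    rr = file.path(dir, paste0(stem, "_rr.csv"))
  )
  readr::write_csv(register$eda, paths[["eda"]])
  readr::write_csv(register$rr_beats, paths[["rr"]])
  if (!is.null(register$annotations)) {
    paths[["annotations"]] <- file.path(dir, paste0(stem, "_annotations.csv"))
    readr::write_csv(register$annotations, paths[["annotations"]])
  }
  invisible(paths)
}

#' @export
print.physio_register <- function(x, ...) {
  span <- register_span(x)
  cat(sprintf("<physio_register> subject %s\n", x$subject_id))
  cat(sprintf("  EDA: %d samples over %.1f s\n", nrow(x$eda), diff(range(x$eda$t))))
  cat(sprintf("  RR:  %d beats, mean interval %.3f s\n",
              nrow(x$rr_beats), mean(x$rr_beats$rr)))
  cat(sprintf("  common span: [%.2f, %.2f] s\n", span[1], span[2]))
  if (!is.null(x$annotations)) {
    cat(sprintf("  annotations: %d intervals (%s)\n", nrow(x$annotations),
                paste(levels(droplevels(x$annotations$label)), collapse = ", ")))
  }
  if (!is.null(x$rr_grid)) {
    cat(sprintf("  preprocessed: RR grid at %g Hz, EDA low-passed at %g Hz\n",
                x$grid_hz, x$cutoff_hz))
  }
  invisible(x)
}

## first/last instant at which both signals exist
register_span <- function(register) {
  c(max(min(register$eda$t), min(register$rr_beats$beat_time)),
    min(max(register$eda$t), max(register$rr_beats$beat_time)))
}

#' Plot a register's signals and annotations
#'
#' @param object A [physio_register()].
#' @param ... Unused.
#' @return A ggplot with one facet per signal; annotation intervals are
#'   shaded by class.
#' @exportS3Method ggplot2::autoplot
autoplot.physio_register <- function(object, ...) {
  sig <- dplyr::bind_rows(
    tibble::tibble(t = object$eda$t, value = object$eda$eda, signal = "EDA (uS)"),
    tibble::tibble(t = object$rr_beats$beat_time, value = object$rr_beats$rr,
                   signal = "RR (s)")
  )
  p <- ggplot2::ggplot(sig, ggplot2::aes(x = .data$t, y = .data$value))
  if (!is.null(object$annotations)) {
    p <- p + ggplot2::geom_rect(
      data = object$annotations,
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                   ymin = -Inf, ymax = Inf, fill = .data$label),
      alpha = 0.15, inherit.aes = FALSE
    ) +
      ggplot2::scale_fill_manual(
        values = c("Relax-RResp" = "#2c7fb8", "Basal-RResp" = "#31a354",
                   "Stress-RResp" = "#de2d26"),
        name = NULL, drop = FALSE
      )
  }
  p +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = paste("Register", object$subject_id))
}
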