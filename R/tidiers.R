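#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a detection result
#'
#' One row per detected beat with all 11 fiducials (1-based sample
#' indices), polarities and flags; `n_frag` counts additional fragmented
#' R-peaks and `n_mapped` the fiducials substituted by mapping.
#'
#' @param x An `ecg_detection` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ecg_detection
#' @export
tidy.ecg_detection <- function(x, ...) {
  b <- x$beats
  if (nrow(b) == 0) return(b)
  dplyr::mutate(
    b,
    n_frag = lengths(.data$additional_left) + lengths(.data$additional_right),
    n_mapped = lengths(.data$mapped)
  )
}

#' Summarize a detection result
#'
#' @param x An `ecg_detection` object.
#' @param ... Unused.
#' @return One-row tibble with beat counts, polarity/fragment tallies and
#'   the mean heart rate implied by the RR series.
#' @method glance ecg_detection
#' @export
glance.ecg_detection <- function(x, ...) {
  b <- x$beats
  rr <- rr_intervals(x)
  tibble::tibble(
    n_beats = nrow(b),
    n_inverted = sum(b$gamma < 0),
    n_fragmented = sum(lengths(b$additional_left) +
                         lengths(b$additional_right) > 0),
    n_mapped_beats = sum(lengths(b$mapped) > 0),
    duration_s = nrow(x$record) / x$fs,
    hr_mean_bpm = if (nrow(rr)) mean(60 / rr$interval) else NA_real_
  )
}

#' Plot a detection result
#'
#' The ECG trace with the detected fiducials overlaid; peaks as points,
#' onsets/offsets as open triangles, additional fragmented R-peaks as
#' crosses.
#'
#' @param object An `ecg_detection` object.
#' @param xlim Optional two-element sample range to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ecg_detection
#' @export
autoplot.ecg_detection <- function(object, xlim = NULL, ...) {
  rec <- object$record
  b <- object$beats
  if (!is.null(xlim)) {
    rec <- dplyr::filter(rec, .data$sample >= xlim[1], .data$sample <= xlim[2])
    b <- dplyr::filter(b, .data$r_peak >= xlim[1], .data$r_peak <= xlim[2])
  }
  long <- tidyr::pivot_longer(
    b[, c("beat_id", fiducial_cols)],
    cols = dplyr::all_of(fiducial_cols),
    names_to = "fiducial", values_to = "sample"
  )
  long$mv <- rec$mv[match(long$sample, rec$sample)]
  long$kind <- ifelse(grepl("onset|offset", long$fiducial), "bound", "peak")
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$sample, y = .data$mv)) +
    ggplot2::geom_line(color = "grey40", linewidth = 0.3) +
    ggplot2::geom_point(
      data = long,
      ggplot2::aes(color = .data$fiducial, shape = .data$kind),
      size = 2, na.rm = TRUE
    ) +
    ggplot2::scale_shape_manual(values = c(peak = 16, bound = 2)) +
    ggplot2::labs(x = "sample", y = "mV", color = "fiducial", shape = NULL) +
    ggplot2::theme_minimal()
}

#' Plot interval trends
#'
#' ST-segment, PR-interval and QT-interval per beat, faceted.
#'
#' @param det An `ecg_detection` object.
#' @return A ggplot object.
#' @export
plot_interval_trends <- function(det) {
  tr <- interval_trends(det)
  long <- tidyr::pivot_longer(tr, c("st", "pr", "qt"),
                              names_to = "interval", values_to = "seconds")
  ggplot2::ggplot(long, ggplot2::aes(.data$beat_id, .data$seconds)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~interval, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "beat", y = "seconds") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
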