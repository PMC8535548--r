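#' Plan sliding windows over a record
#'
#' Half-open spans `[k*step + 1, k*step + window_len]` (1-based, inclusive)
#' clipped to the record end. Consecutive spans overlap by `window_len -
#' step` samples; the final window may be short.
#'
#' @param record_length Record length in samples (>= 1).
#' @param window_len,step Window length and step in samples; `step` must be
#'   smaller than `window_len` so an overlap exists.
#' @return Tibble with columns `start`, `end` (inclusive sample indices).
#' @export
#' @examples
#' segment_windows(3600, 2000, 1600)  # two windows overlapping by 400
segment_windows <- function(record_length, window_len = 2000, step = 1600) {
  stopifnot(record_length >= 1, step >= 1, step < window_len)
  starts <- seq.int(1L, max(1L, record_length), by = step)
  starts <- starts[starts <= record_length]
  # drop trailing windows fully contained in the previous one
  keep <- c(TRUE, (starts[-1] + window_len - 1L) >
              (starts[-length(starts)] + window_len - 1L)) &
    c(TRUE, starts[-1] <= record_length)
  starts <- starts[keep]
  ends <- pmin(starts + window_len - 1L, record_length)
  redundant <- c(FALSE, ends[-1] <= ends[-length(ends)])
  tibble::tibble(start = as.integer(starts[!redundant]),
                 end = as.integer(ends[!redundant]))
}

# run the full per-window detector; returns beats with window-local indices
detect_window <- function(raw, config) {
  n <- length(raw)
  empty <- beats_prototype()
  if (n < 3 || diff(range(raw)) == 0) return(empty)

  I <- normalize_window(raw, mode = config$normalization)
  B <- bilateral_filter(I$samples, config$filter)
  D <- I$samples - B
  E <- enhance_residual(D, config$enhance_n)
  runs <- candidate_r_intervals(E, min_run = config$min_run)
  if (!length(runs)) return(empty)

  rinfo <- purrr::map(runs, function(run) {
    r <- locate_r_peak(I, run)
    r$additional_left <- detect_additional_r(I, r, "left", config)
    r$additional_right <- detect_additional_r(I, r, "right", config)
    r
  })
  r_order <- order(purrr::map_int(rinfo, "index"))
  rinfo <- rinfo[r_order]
  r_idx <- purrr::map_int(rinfo, "index")

  beats <- vector("list", length(rinfo))
  prev_t_offset <- 0L
  for (b in seq_along(rinfo)) {
    r <- rinfo[[b]]
    next_r <- if (b < length(rinfo)) r_idx[b + 1L] else n + 1L
    beat <- delineate_beat(I, B, r, config,
                           prev_t_offset = prev_t_offset,
                           next_r = next_r)
    prev_t_offset <- beat$t_offset
    beats[[b]] <- beat
  }
  beats_to_tibble(beats)
}

# Q/S on the normalized signal, P/T on the predicted background, then the
# polarity selection and missing-point mapping. All indices window-local.
delineate_beat <- function(I, B, r, config, prev_t_offset, next_r) {
  n <- length(I$samples)
  gamma <- r$gamma
  rl <- min(c(r$index, r$additional_left))
  rr <- max(c(r$index, r$additional_right))

  q <- detect_q(I, rl, gamma, config)
  q_on <- detect_q_onset(I, q$index, gamma, config)
  s <- detect_s(I, rr, gamma, config, limit = next_r - 1L)
  s_off <- detect_s_offset(I, s$index, gamma, config, limit = next_r - 1L)

  # T-wave: rightward from S-offset within alpha_t, capped by the next R
  t_limit <- min(s_off$index + config$alpha_t, next_r - 1L, n)
  t_cand <- purrr::map(c(1L, -1L), function(om) {
    pk <- detect_wave_peak(B, s_off$index, "right", config$alpha_t, om,
                           config$wing_t, config$v_t_max, config$rho_t,
                           limit = t_limit)
    if (is.null(pk)) return(NULL)
    alpha_tr <- (pk$index - 1L) - s_off$index
    pk$onset <- detect_wave_bounds(B, pk$index, om, pk$v_true, "onset",
                                   lower = s_off$index + 1L,
                                   upper = pk$index)
    pk$offset <- detect_wave_bounds(B, pk$index, om, pk$v_true, "offset",
                                    lower = pk$index,
                                    upper = min(pk$index + alpha_tr,
                                                next_r - 1L, n))
    pk
  })
  t_sel <- select_wave_polarity(t_cand[[1]], t_cand[[2]], B)

  # P-wave: leftward from Q-onset within alpha_p, floored by the previous
  # T-offset (empty range at high heart rate => mapped)
  p_lo <- max(q_on$index - config$alpha_p, prev_t_offset + 1L, 1L)
  p_sel <- NULL
  if (q_on$index - 1L >= p_lo) {
    p_cand <- purrr::map(c(1L, -1L), function(om) {
      pk <- detect_wave_peak(B, q_on$index, "left", config$alpha_p, om,
                             config$wing_p, config$v_p_max, config$rho_p,
                             limit = p_lo)
      if (is.null(pk)) return(NULL)
      alpha_pl <- (q_on$index - 1L) - pk$index
      pk$onset <- detect_wave_bounds(B, pk$index, om, pk$v_true, "onset",
                                     lower = max(pk$index - alpha_pl,
                                                 prev_t_offset + 1L, 1L),
                                     upper = pk$index)
      pk$offset <- detect_wave_bounds(B, pk$index, om, pk$v_true, "offset",
                                      lower = pk$index,
                                      upper = q_on$index - 1L)
      pk
    })
    p_sel <- select_wave_polarity(p_cand[[1]], p_cand[[2]], B)
  }

  beat <- list(
    r_peak = r$index, gamma = gamma, is_flat = r$is_flat,
    additional_left = r$additional_left,
    additional_right = r$additional_right,
    q_peak = q$index, q_onset = q_on$index,
    s_peak = s$index, s_offset = s_off$index,
    p_peak = p_sel$index %||% NA_integer_,
    p_onset = p_sel$onset %||% NA_integer_,
    p_offset = p_sel$offset %||% NA_integer_,
    omega_p = p_sel$omega %||% NA_integer_,
    v_p = p_sel$v_true %||% NA_integer_,
    t_peak = t_sel$index %||% NA_integer_,
    t_onset = t_sel$onset %||% NA_integer_,
    t_offset = t_sel$offset %||% NA_integer_,
    omega_t = t_sel$omega %||% NA_integer_,
    v_t = t_sel$v_true %||% NA_integer_,
    mapped = c(
      if (q$mapped) "q_peak", if (q_on$mapped) "q_onset",
      if (s$mapped) "s_peak", if (s_off$mapped) "s_offset"
    )
  )
  map_missing_fps(beat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fiducial_cols <- c(
  "p_onset", "p_peak", "p_offset", "q_onset", "q_peak", "r_peak",
  "s_peak", "s_offset", "t_onset", "t_peak", "t_offset"
)

beats_prototype <- function() {
  tibble::tibble(
    p_onset = integer(0), p_peak = integer(0), p_offset = integer(0),
    q_onset = integer(0), q_peak = integer(0), r_peak = integer(0),
    s_peak = integer(0), s_offset = integer(0),
    t_onset = integer(0), t_peak = integer(0), t_offset = integer(0),
    gamma = integer(0), omega_p = integer(0), omega_t = integer(0),
    v_p = integer(0), v_t = integer(0), is_flat = logical(0),
    additional_left = list(), additional_right = list(), mapped = list()
  )
}

beats_to_tibble <- function(beats) {
  if (!length(beats)) return(beats_prototype())
  purrr::map_dfr(beats, function(b) {
    tibble::tibble(
      p_onset = as.integer(b$p_onset), p_peak = as.integer(b$p_peak),
      p_offset = as.integer(b$p_offset), q_onset = as.integer(b$q_onset),
      q_peak = as.integer(b$q_peak), r_peak = as.integer(b$r_peak),
      s_peak = as.integer(b$s_peak), s_offset = as.integer(b$s_offset),
      t_onset = as.integer(b$t_onset), t_peak = as.integer(b$t_peak),
      t_offset = as.integer(b$t_offset),
      gamma = as.integer(b$gamma),
      omega_p = as.integer(b$omega_p), omega_t = as.integer(b$omega_t),
      v_p = as.integer(b$v_p), v_t = as.integer(b$v_t),
      is_flat = isTRUE(b$is_flat),
      additional_left = list(as.integer(b$additional_left)),
      additional_right = list(as.integer(b$additional_right)),
      mapped = list(as.character(b$mapped))
    )
  })
}

#' Stitch per-window beats into one record-level annotation stream
#'
#' Beats reported by overlapping windows are matched on their R-peak within
#' the tolerance and collapsed to one beat per group. Beats whose R-peak
#' lies at least half the fragment search range away from both window edges
#' are "perfect" (all fiducials trustworthy); within a group, a perfect beat
#' from the earliest window is the seam reference and wins, otherwise the
#' earliest window's beat is kept. The output R-peaks are strictly
#' increasing with no two closer than the tolerance. Stitching an already
#' stitched table is the identity.
#'
#' @param beats Tibble of beats with absolute indices; columns
#'   `window_start`/`window_end` mark each beat's source window (absent
#'   columns mean every beat is perfect, e.g. a single window).
#' @param fs Sampling rate in Hz.
#' @param tolerance_ms Matching tolerance in milliseconds (default 50).
#' @param margin Edge margin in samples defining a perfect beat; default
#'   `round(0.44 * fs)`, the typical QT time -- the farthest any fiducial of
#'   a beat extends from its R-peak, so a "perfect" beat has room for all 11
#'   fiducials inside its window.
#' @return Tibble of stitched beats sorted by `r_peak`.
#' @export
stitch_annotations <- function(beats, fs, tolerance_ms = 50, margin = NULL) {
  if (nrow(beats) == 0) return(beats)
  if (is.null(margin)) margin <- round(0.44 * fs)
  tol <- round(tolerance_ms / 1000 * fs)

  has_win <- all(c("window_start", "window_end") %in% names(beats))
  if (has_win) {
    beats$.perfect <- beats$r_peak - beats$window_start >= margin &
      beats$window_end - beats$r_peak >= margin
    # records shorter than a window (or ends of record): no other window can
    # cover these beats, keep them regardless of margin
    beats$.perfect <- beats$.perfect |
      (beats$r_peak - min(beats$window_start) < margin) |
      (max(beats$window_end) - beats$r_peak < margin)
    ord <- order(beats$r_peak, beats$window_start)
  } else {
    beats$.perfect <- TRUE
    ord <- order(beats$r_peak)
  }
  beats <- beats[ord, , drop = FALSE]

  # group consecutive beats whose R-peaks agree within the tolerance
  grp <- cumsum(c(1L, as.integer(diff(beats$r_peak) > tol)))
  keep_rows <- vapply(split(seq_len(nrow(beats)), grp), function(rows) {
    cand <- beats[rows, , drop = FALSE]
    pref <- which(cand$.perfect)
    if (!length(pref)) pref <- seq_len(nrow(cand))
    if (has_win) {
      rows[pref[which.min(cand$window_start[pref])]]
    } else {
      rows[pref[1L]]
    }
  }, integer(1))
  out <- beats[sort(keep_rows), , drop = FALSE]
  out$.perfect <- NULL
  out
}

#' Detect the PQRST fiducials of a single-lead ECG record
#'
#' The main entry point: segments the record into overlapping sliding
#' windows, predicts the background of each window with the adaptive
#' bilateral filter, detects R-peaks (with polarity, flat tops and
#' fragmented notches) from the enhanced residual, delineates Q, Q-onset, S,
#' S-offset on the normalized signal and the P/T peaks, onsets and offsets
#' on the background, maps undetected fiducials, and stitches the
#' per-window beats into one record-level stream.
#'
#' @param data Data frame with a numeric `mv` column (one sample per row),
#'   or a bare numeric vector of millivolt samples.
#' @param fs Sampling rate in Hz (required).
#' @param config [detector_config()]; defaults to the standard constants
#'   resolved for `fs`.
#' @return An object of class `"ecg_detection"`: a list with `beats` (tibble,
#'   one row per beat, all indices 1-based record positions), `record`,
#'   `fs`, `config` and `windows`. Use [tidy()][generics::tidy] for the beat
#'   table, [glance()][generics::glance] for a one-row summary and
#'   [autoplot()][ggplot2::autoplot] for an annotated trace.
#' @export
#' @examples
#' rec <- synthesize_record(n_beats = 8, seed = 1)
#' det <- ecg_detect(rec$record, fs = rec$fs)
#' glance(det)
ecg_detect <- function(data, fs, config = detector_config(fs)) {
  if (missing(fs) || is.null(fs)) stop("`fs` is required", call. = FALSE)
  mv <- if (is.data.frame(data)) {
    if (!"mv" %in% names(data)) stop("`data` must have an `mv` column", call. = FALSE)
    data$mv
  } else {
    as.numeric(data)
  }
  n <- length(mv)
  plan <- segment_windows(n, config$window_len, config$step)

  per_window <- purrr::pmap_dfr(plan, function(start, end) {
    wb <- detect_window(mv[start:end], config)
    if (nrow(wb) == 0) return(wb)
    shift <- start - 1L
    for (col in fiducial_cols) wb[[col]] <- wb[[col]] + shift
    wb$additional_left <- purrr::map(wb$additional_left, ~ .x + shift)
    wb$additional_right <- purrr::map(wb$additional_right, ~ .x + shift)
    wb$window_start <- start
    wb$window_end <- end
    wb
  })

  beats <- stitch_annotations(per_window, fs, config$tolerance_ms)
  if (nrow(beats)) beats$beat_id <- seq_len(nrow(beats))
  structure(
    list(
      beats = beats,
      record = tibble::tibble(sample = seq_len(n), mv = mv),
      fs = fs,
      config = config,
      windows = plan
    ),
    class = "ecg_detection"
  )
}

#' @export
print.ecg_detection <- function(x, ...) {
  cat("<ecg_detection> ", nrow(x$beats), " beats over ",
      nrow(x$record), " samples at ", x$fs, " Hz (",
      nrow(x$windows), " windows)\n", sep = "")
  if (nrow(x$beats)) {
    inv <- sum(x$beats$gamma < 0)
    frag <- sum(lengths(x$beats$additional_left) +
                  lengths(x$beats$additional_right) > 0)
    cat("  inverted R:", inv, " fragmented:", frag, "\n")
  }
  invisible(x)
}
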