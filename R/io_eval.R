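#' Match detected beats against annotations
#'
#' Greedy one-to-one matching by increasing absolute time difference: a
#' detected/annotated pair matches when it differs by strictly less than the
#' tolerance (50 ms by convention). Unmatched annotations count as false
#' negatives, unmatched detections as false positives. The tolerance is in
#' milliseconds, so counts are invariant to the sampling rate, and swapping
#' the two inputs swaps FN and FP.
#'
#' @param detected,truth Sorted sample indices of detected and annotated
#'   R-peaks.
#' @param fs Sampling rate in Hz.
#' @param tolerance_ms Matching tolerance (ms), exclusive.
#' @return One-row tibble with `total` (annotations), `tp`, `fn`, `fp`;
#'   `tp + fn == total`.
#' @export
#' @examples
#' match_annotations(c(110), c(100), fs = 360)       # 27.8 ms -> TP
#' match_annotations(c(120), c(100), fs = 360)       # 55.6 ms -> FN + FP
match_annotations <- function(detected, truth, fs, tolerance_ms = 50) {
  detected <- sort(as.numeric(detected))
  truth <- sort(as.numeric(truth))
  tol_samples <- tolerance_ms / 1000 * fs
  if (length(detected) && length(truth)) {
    dmat <- abs(outer(detected, truth, `-`))
    pairs <- which(dmat < tol_samples, arr.ind = TRUE)
    if (nrow(pairs)) {
      pairs <- pairs[order(dmat[pairs]), , drop = FALSE]
      used_d <- logical(length(detected))
      used_t <- logical(length(truth))
      tp <- 0L
      for (k in seq_len(nrow(pairs))) {
        i <- pairs[k, 1]
        j <- pairs[k, 2]
        if (!used_d[i] && !used_t[j]) {
          used_d[i] <- used_t[j] <- TRUE
          tp <- tp + 1L
        }
      }
    } else {
      tp <- 0L
    }
  } else {
    tp <- 0L
  }
  tibble::tibble(
    total = length(truth),
    tp = tp,
    fn = length(truth) - tp,
    fp = length(detected) - tp
  )
}

#' Detection performance metrics
#'
#' Sensitivity `Se = 100 * TP / (TP + FN)`, positive prediction
#' `+P = 100 * TP / (TP + FP)` and detection error rate
#' `DER = 100 * (FP + FN) / (TP + FN)`, all in percent.
#'
#' @param counts Tibble or list with `tp`, `fn`, `fp` (as from
#'   [match_annotations()]); multiple rows are summed first.
#' @return One-row tibble with `se`, `pp`, `der` (percent). Zero
#'   denominators yield `NA`.
#' @export
#' @examples
#' detection_metrics(tibble::tibble(tp = 109326, fn = 184, fp = 193))
detection_metrics <- function(counts) {
  tp <- sum(counts$tp)
  fn <- sum(counts$fn)
  fp <- sum(counts$fp)
  if (tp + fn == 0) stop("no annotated beats: tp + fn must be > 0", call. = FALSE)
  tibble::tibble(
    se = 100 * tp / (tp + fn),
    pp = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
    der = 100 * (fp + fn) / (tp + fn)
  )
}

#' Delineation error statistics
#'
#' Mean `m`, population standard deviation `s` and the combined
#' root-mean-square error `RMSE = sqrt(m^2 + s^2)` of signed localization
#' errors (detected minus annotated, milliseconds).
#'
#' @param errors_ms Non-empty numeric vector of signed errors (ms).
#' @return One-row tibble with `m`, `s`, `rmse` (ms) and `n`.
#' @export
#' @examples
#' rmse_stats(c(-1.5, 1.8 + 3.3, 1.8 - 3.3, 5.1))
rmse_stats <- function(errors_ms) {
  if (length(errors_ms) == 0 || anyNA(errors_ms)) {
    stop("`errors_ms` must be non-empty without NA", call. = FALSE)
  }
  m <- mean(errors_ms)
  s <- sqrt(mean((errors_ms - m)^2))
  tibble::tibble(m = m, s = s, rmse = sqrt(m^2 + s^2), n = length(errors_ms))
}

#' Read / write ECG records as CSV
#'
#' The record format is a two-column CSV `sample_index,mv` with 0-based
#' sample indices; the sampling rate is not stored in the file and must
#' always be given explicitly (it is never guessed).
#'
#' @param path File path.
#' @param fs Sampling rate in Hz; required on read.
#' @return `read_ecg_csv()`: tibble with `sample` (1-based), `mv`, and the
#'   sampling rate in attribute `fs`. `write_ecg_csv()`: the input,
#'   invisibly.
#' @export
read_ecg_csv <- function(path, fs) {
  if (missing(fs) || is.null(fs)) {
    stop("`fs` is required: the CSV record format does not store the sampling rate",
         call. = FALSE)
  }
  df <- utils::read.csv(path)
  if (ncol(df) < 2) stop("malformed record file: expected 2 columns in ", path, call. = FALSE)
  names(df)[1:2] <- c("sample_index", "mv")
  if (anyNA(df$mv) || anyNA(df$sample_index)) {
    bad <- which(is.na(df$mv) | is.na(df$sample_index))[1]
    stop("malformed record file at data line ", bad, " of ", path, call. = FALSE)
  }
  out <- tibble::tibble(sample = as.integer(df$sample_index) + 1L,
                        mv = as.numeric(df$mv))
  attr(out, "fs") <- fs
  out
}

#' @rdname read_ecg_csv
#' @param record Tibble with `sample` (1-based) and `mv` columns.
#' @export
write_ecg_csv <- function(record, path) {
  # %.17g keeps the round trip bit-exact for doubles
  utils::write.csv(
    data.frame(sample_index = record$sample - 1L,
               mv = sprintf("%.17g", record$mv)),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(record)
}

#' Read / write per-beat fiducials as JSON
#'
#' Serializes a beats table as one JSON record per beat:
#' `{beat_id, fs, fiducials: {name: sample_index}, gamma, omega_p, omega_t,
#' mapped: [...]}`. Sample indices are 0-based on disk and converted back to
#' 1-based on read.
#'
#' @param beats Beats tibble (as in an `ecg_detection`).
#' @param fs Sampling rate in Hz.
#' @param path File path.
#' @return `read_fiducials_json()`: list with `beats` tibble and `fs`.
#'   `write_fiducials_json()`: the input, invisibly.
#' @export
write_fiducials_json <- function(beats, fs, path) {
  cols <- c(fiducial_cols, "gamma", "omega_p", "omega_t", "mapped", "beat_id")
  cols <- cols[cols %in% names(beats)]
  recs <- purrr::pmap(beats[, cols], function(...) {
    row <- list(...)
    fid <- purrr::map(row[fiducial_cols], ~ .x - 1L)
    list(
      beat_id = row$beat_id %||% NA_integer_,
      fs = fs,
      fiducials = fid,
      gamma = row$gamma,
      omega_p = row$omega_p,
      omega_t = row$omega_t,
      mapped = as.character(row$mapped %||% character(0))
    )
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(beats)
}

#' @rdname write_fiducials_json
#' @export
read_fiducials_json <- function(path) {
  recs <- jsonlite::read_json(path)
  beats <- purrr::map_dfr(recs, function(r) {
    fid <- purrr::map(r$fiducials, ~ as.integer(.x) + 1L)
    tibble::tibble(
      beat_id = r$beat_id %||% NA_integer_,
      !!!fid,
      gamma = as.integer(r$gamma %||% NA_integer_),
      omega_p = as.integer(r$omega_p %||% NA_integer_),
      omega_t = as.integer(r$omega_t %||% NA_integer_),
      mapped = list(as.character(unlist(r$mapped)))
    )
  })
  fs <- if (length(recs)) recs[[1]]$fs else NA_real_
  list(beats = beats, fs = fs)
}
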