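#' Normalize a sliding-window ECG segment
#'
#' Maps a raw millivolt window onto a dimensionless scale before background
#' prediction. The default mode is min-max scaling `(S - Smin)/(Smax -
#' Smin)`, which lands exactly in `[0, 1]` for any baseline; `"literal"`
#' divides the min-subtracted signal by the raw window maximum instead.
#' Detection thresholds (Thc, Thf) are defined on this normalized scale, so
#' multiplying the raw signal by any positive gain leaves all detected
#' indices unchanged.
#'
#' @param raw_samples Non-constant numeric vector of raw samples (mV).
#' @param mode `"minmax"` (default) or `"literal"`.
#' @return List with `samples` (normalized vector) and `mean_value`
#'   (the window mean of the normalized signal, used for polarity decisions).
#' @export
#' @examples
#' normalize_window(c(0, 5, 10))$samples   # 0, 0.5, 1
normalize_window <- function(raw_samples, mode = c("minmax", "literal")) {
  mode <- match.arg(mode)
  if (length(raw_samples) == 0 || anyNA(raw_samples)) {
    stop("`raw_samples` must be non-empty without NA", call. = FALSE)
  }
  smin <- min(raw_samples)
  smax <- max(raw_samples)
  if (smax - smin == 0) {
    stop("degenerate signal: window is constant, cannot normalize", call. = FALSE)
  }
  denom <- if (mode == "minmax") smax - smin else smax
  if (denom == 0) stop("degenerate signal: window maximum is zero", call. = FALSE)
  s <- (raw_samples - smin) / denom
  list(samples = s, mean_value = mean(s))
}

#' Enhanced residual signal
#'
#' Moving sum of the residual `D = I - B` over a `2n + 1` window,
#' zero-padded (truncated) at the boundaries. Summing widens and reinforces
#' the QRS residual so candidate-R runs comfortably clear the minimum run
#' length.
#'
#' @param D Numeric residual vector.
#' @param n Non-negative integer half-width; `n = 0` returns `D` unchanged.
#' @return Numeric vector of the same length as `D`.
#' @export
#' @examples
#' enhance_residual(c(0, 0, 1, 0, 0), 1)  # 0 1 1 1 0
enhance_residual <- function(D, n) {
  stopifnot(n >= 0)
  if (n == 0) return(D)
  len <- length(D)
  cs <- cumsum(c(0, D))
  hi <- pmin(len, seq_len(len) + n)
  lo <- pmax(1L, seq_len(len) - n)
  cs[hi + 1L] - cs[lo]
}

#' Candidate-R intervals from the enhanced residual
#'
#' Finds maximal runs of consecutive samples whose enhanced-residual
#' magnitude exceeds the threshold. The magnitude `|E|` is thresholded (with
#' the default `max(|E|)/2` rule) so inverted R-waves, whose residual lobe is
#' negative, produce candidate runs exactly like upright ones; the polarity
#' itself is decided later by [locate_r_peak()]. Runs shorter than `min_run`
#' are discarded.
#'
#' @param E Numeric enhanced residual.
#' @param threshold Positive threshold; defaults to `max(abs(E))/2`.
#' @param min_run Minimum run length L (default 8).
#' @return List of integer index vectors, one per accepted run, in
#'   increasing order. May be empty.
#' @export
#' @examples
#' E <- c(rep(0, 5), rep(1, 9), rep(0, 5))
#' candidate_r_intervals(E, threshold = 0.5, min_run = 8)
candidate_r_intervals <- function(E, threshold = NULL, min_run = 8) {
  stopifnot(length(E) > 0, min_run >= 1)
  if (is.null(threshold)) threshold <- max(abs(E)) / 2
  above <- abs(E) > threshold
  if (!any(above)) return(list())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  purrr::map2(starts[keep], ends[keep], seq.int)
}

#' Locate the R-peak within a candidate run
#'
#' Decides polarity by comparing the run's excursion above and below the
#' window mean: if `max(I) - Imean >= Imean - min(I)` the beat is upright
#' (`gamma = +1`) and the R-peak is the argmax, otherwise it is inverted
#' (`gamma = -1`, e.g. a premature ventricular contraction) and the R-peak is
#' the argmin. Ties between equal extrema (a flat-topped R) resolve to the
#' floor of their average position and set the flat flag.
#'
#' @param I Normalized window as returned by [normalize_window()], or a list
#'   with `samples` and `mean_value`.
#' @param run Integer indices of one candidate run (inside `I$samples`).
#' @return List with `index`, `gamma` (+1/-1) and `is_flat`.
#' @export
locate_r_peak <- function(I, run) {
  stopifnot(length(run) > 0, all(run >= 1), all(run <= length(I$samples)))
  vals <- I$samples[run]
  imean <- I$mean_value
  if ((max(vals) - imean) >= (imean - min(vals))) {
    gamma <- 1L
    tied <- run[vals == max(vals)]
  } else {
    gamma <- -1L
    tied <- run[vals == min(vals)]
  }
  list(
    index = as.integer(floor(mean(tied))),
    gamma = gamma,
    is_flat = length(tied) > 1L
  )
}

# backward slope sign: s[t] = sign(I[t] - I[t+1]); length(s) = length(x) - 1
slope_sign <- function(x) sign(x[-length(x)] - x[-1L])

# rebound sum of up to 10 successive point-pair differences away from p.
# right side telescopes to I(p) + I(p+1) - I(p+10) - I(p+11); the left side
# is its mirror. Runs that fall off the window are truncated (partial sums).
frag_rebound_sum <- function(x, p, side) {
  n <- length(x)
  total <- 0
  for (m in 1:10) {
    if (side == "right") {
      a <- p + m - 1L
      b <- p + m + 1L
      if (b > n) break
    } else {
      a <- p - m + 1L
      b <- p - m - 1L
      if (b < 1L) break
    }
    total <- total + (x[a] - x[b])
  }
  total
}

#' Detect additional (fragmented) R-peaks
#'
#' Recursively scans outward from the located R-peak for secondary notch
#' peaks (fR-L, fR-R, fR-L2, fR-R2 patterns). A sample is accepted when the
#' gamma-oriented slope sign flips from rising to falling (a gamma-oriented
#' local maximum, evaluated on `I'(t) = I(t) - I(t+1)`) and the
#' gamma-oriented sum of 10 successive point-pair differences away from the
#' candidate exceeds `thf` (default 0.1 on the normalized scale). After each
#' acceptance the scan continues within `alpha_f` samples of the newest peak,
#' so multiple notches are found in order.
#'
#' @param I Normalized window (list with `samples`).
#' @param r R-peak info from [locate_r_peak()] (list with `index`, `gamma`),
#'   or a bare index plus `gamma`.
#' @param side `"left"` or `"right"` of the R-peak.
#' @param config [detector_config()]; uses `alpha_f` and `thf`.
#' @return Integer vector of accepted indices in scan order (possibly empty).
#' @export
detect_additional_r <- function(I, r, side = c("right", "left"),
                                config = detector_config()) {
  side <- match.arg(side)
  x <- I$samples
  n <- length(x)
  gamma <- r$gamma
  anchor <- r$index
  found <- integer(0)
  s <- slope_sign(x)
  step <- if (side == "right") 1L else -1L
  p <- anchor + step
  repeat {
    if (abs(p - anchor) > config$alpha_f) break
    if (p < 2L || p > n - 1L) break              # slope needs both neighbors
    is_peak <- gamma * s[p - 1L] <= 0 && gamma * s[p] >= 0
    if (is_peak) {
      reb <- gamma * frag_rebound_sum(x, p, side)
      if (reb > config$thf) {
        found <- c(found, p)
        anchor <- p                               # recursion: extend range
      }
    }
    p <- p + step
  }
  found
}
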