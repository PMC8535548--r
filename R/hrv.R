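#' RR (NN) interval series from detected beats
#'
#' @param x An `ecg_detection` object, a beats tibble with an `r_peak`
#'   column, or a bare vector of R-peak sample indices.
#' @param fs Sampling rate in Hz (taken from the detection object when
#'   available).
#' @return Tibble with `interval` (seconds between successive R-peaks) and
#'   `time` (seconds of each interval's end).
#' @export
rr_intervals <- function(x, fs = NULL) {
  r <- if (inherits(x, "ecg_detection")) {
    fs <- x$fs
    x$beats$r_peak
  } else if (is.data.frame(x)) {
    x$r_peak
  } else {
    as.numeric(x)
  }
  if (is.null(fs)) stop("`fs` is required", call. = FALSE)
  r <- sort(r)
  if (length(r) < 2) {
    return(tibble::tibble(interval = numeric(0), time = numeric(0)))
  }
  tibble::tibble(interval = diff(r) / fs, time = r[-1] / fs)
}

#' Time-domain HRV metrics
#'
#' Summary statistics of an RR series: mean and standard deviation of the
#' RR intervals (s) and of the instantaneous heart rate `60/RR` (bpm), the
#' NN50 count (adjacent-interval changes strictly larger than 50 ms), pNN50
#' (`100 * NN50 / (n - 1)`), RMSSD (root mean square of successive
#' differences, ms), the HRV triangular index HTI (number of intervals
#' divided by the peak bin count of the RR histogram) and TINN (baseline
#' width of the least-squares triangle fitted over that histogram, ms). The
#' histogram bin width is the conventional 1/128 s.
#'
#' @param rr RR series from [rr_intervals()], or a numeric vector of
#'   intervals in seconds.
#' @param bin_width_s Histogram bin width in seconds for HTI/TINN.
#' @return One-row tibble with `rr_mean`, `rr_std` (s), `hr_mean`, `hr_std`
#'   (bpm), `nn50`, `pnn50` (%), `rmssd` (ms), `hti`, `tinn` (ms).
#' @export
#' @examples
#' hrv_time(c(0.800, 0.860, 0.800, 0.860))
hrv_time <- function(rr, bin_width_s = 1 / 128) {
  x <- if (is.data.frame(rr)) rr$interval else as.numeric(rr)
  if (length(x) < 2) stop("insufficient data: need at least 2 intervals", call. = FALSE)
  d <- diff(x)
  hr <- 60 / x

  breaks <- seq(floor(min(x) / bin_width_s) * bin_width_s,
                max(x) + bin_width_s, by = bin_width_s)
  counts <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts

  tibble::tibble(
    rr_mean = mean(x),
    rr_std = stats::sd(x),
    hr_mean = mean(hr),
    hr_std = stats::sd(hr),
    nn50 = sum(abs(d) > 0.050),
    pnn50 = 100 * sum(abs(d) > 0.050) / length(d),
    rmssd = sqrt(mean(d^2)) * 1000,
    hti = length(x) / max(counts),
    tinn = tinn_width(counts, bin_width_s) * 1000
  )
}

# least-squares triangular interpolation of the RR histogram: choose bin
# edges N <= peak <= M minimizing the squared error between the histogram
# and a triangle rising linearly from 0 at N to the peak count and back to
# 0 at M. Returns the baseline width M - N in seconds; 0 when only one bin
# is occupied.
tinn_width <- function(counts, bin_width_s) {
  k <- length(counts)
  if (sum(counts > 0) <= 1) return(0)
  peak <- which.max(counts)
  y <- counts
  best <- Inf
  best_w <- 0
  for (N in 1:peak) {
    for (M in peak:k) {
      if (M - N < 1) next
      tri <- numeric(k)
      if (peak > N) {
        i <- N:peak
        tri[i] <- y[peak] * (i - N) / (peak - N)
      } else {
        tri[peak] <- y[peak]
      }
      if (M > peak) {
        i <- peak:M
        tri[i] <- y[peak] * (M - i) / (M - peak)
      }
      err <- sum((y - tri)^2)
      if (err < best) {
        best <- err
        best_w <- (M - N) * bin_width_s
      }
    }
  }
  best_w
}

#' Frequency-domain HRV metrics
#'
#' Band powers of the RR tachogram. The default pipeline interpolates the
#' interval series (ms) onto a uniform grid (4 Hz), removes the mean and
#' estimates the power spectral density with Welch-averaged Hann-windowed
#' periodograms (segments of up to 120 s, 50% overlap); powers are
#' integrated over the VLF (0--0.04 Hz), LF (0.04--0.15 Hz) and HF
#' (0.15--0.40 Hz) bands in ms^2. `method = "direct"` skips the resampling
#' and treats the interval series itself as sampled at the mean beat rate.
#'
#' @param rr RR series from [rr_intervals()] (needs `time` for the default
#'   method), or a numeric vector of intervals in seconds.
#' @param resample_hz Uniform resampling rate of the tachogram (Hz).
#' @param method `"resampled"` (default) or `"direct"`.
#' @return One-row tibble with `vlf_power`, `lf_power`, `hf_power` (ms^2),
#'   `vlf_pct`, `lf_pct`, `hf_pct` (% of total), `lf_norm`, `hf_norm`
#'   (normalized units, denominators excluding VLF) and `lf_hf_ratio`.
#'   Normalized values are `NA` when the total power is zero.
#' @export
#' @examples
#' tt <- seq(0.8, 300, by = 0.8)
#' rr <- tibble::tibble(interval = 0.8 + 0.05 * sin(2 * pi * 0.25 * tt),
#'                      time = tt)
#' hrv_freq(rr)$hf_norm   # a pure 0.25 Hz tone lands in the HF band
hrv_freq <- function(rr, resample_hz = 4, method = c("resampled", "direct")) {
  method <- match.arg(method)
  if (is.data.frame(rr)) {
    x <- rr$interval
    tt <- rr$time
  } else {
    x <- as.numeric(rr)
    tt <- cumsum(x)
  }
  if (length(x) < 4) stop("insufficient data: need at least 4 intervals", call. = FALSE)
  if (max(tt) - min(tt) < 60) {
    warning("less than 60 s of data; frequency-domain HRV is unreliable")
  }
  x_ms <- x * 1000

  if (method == "resampled") {
    grid <- seq(min(tt), max(tt), by = 1 / resample_hz)
    sig <- stats::approx(tt, x_ms, xout = grid)$y
    fs <- resample_hz
  } else {
    sig <- x_ms
    fs <- 1 / mean(x)
  }
  psd <- welch_psd(sig - mean(sig), fs, seg_sec = 120)

  band_power <- function(lo, hi) {
    sel <- psd$freq >= lo & psd$freq < hi
    sum(psd$power[sel]) * psd$df
  }
  vlf <- band_power(0, 0.04)
  lf <- band_power(0.04, 0.15)
  hf <- band_power(0.15, 0.40)
  total <- vlf + lf + hf

  safe <- function(v) if (total > 0) v else NA_real_
  tibble::tibble(
    vlf_power = vlf, lf_power = lf, hf_power = hf,
    vlf_pct = safe(100 * vlf / total),
    lf_pct = safe(100 * lf / total),
    hf_pct = safe(100 * hf / total),
    lf_norm = if (total - vlf > 0) 100 * lf / (total - vlf) else NA_real_,
    hf_norm = if (total - vlf > 0) 100 * hf / (total - vlf) else NA_real_,
    lf_hf_ratio = if (hf > 0) lf / hf else NA_real_
  )
}

# Welch-averaged one-sided periodogram, Hann window, 50% overlap
welch_psd <- function(x, fs, seg_sec = 120) {
  n <- length(x)
  seg <- min(n, round(seg_sec * fs))
  seg <- max(seg, 8)
  step <- max(1, floor(seg / 2))
  starts <- seq(1, max(1, n - seg + 1), by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))
  scale <- fs * sum(w^2)
  nf <- floor(seg / 2)
  acc <- numeric(nf + 1)
  for (s0 in starts) {
    chunk <- x[s0:(s0 + seg - 1)]
    if (anyNA(chunk)) next
    ft <- stats::fft(chunk * w)
    p <- Mod(ft[seq_len(nf + 1)])^2 / scale
    p[2:(nf + 1)] <- 2 * p[2:(nf + 1)]
    if (seg %% 2 == 0) p[nf + 1] <- p[nf + 1] / 2
    acc <- acc + p
  }
  freq <- (0:nf) * fs / seg
  list(freq = freq, power = acc / length(starts), df = fs / seg)
}

#' Per-beat ST-segment, PR-interval and QT-interval trends
#'
#' ST runs from the S-offset to the T-onset, PR from the P-onset to the
#' Q-onset and QT from the Q-onset to the T-offset, each in seconds. Mapped
#' P-waves (e.g. during atrial fibrillation) legitimately yield PR values
#' near zero because all P fiducials collapse onto the Q-onset.
#'
#' @param beats Beats tibble (post-mapping, all 11 fiducials populated) or
#'   an `ecg_detection` object.
#' @param fs Sampling rate in Hz (taken from the detection object when
#'   available).
#' @return Tibble with `beat_id`, `st`, `pr`, `qt` (seconds).
#' @export
interval_trends <- function(beats, fs = NULL) {
  if (inherits(beats, "ecg_detection")) {
    fs <- beats$fs
    beats <- beats$beats
  }
  if (is.null(fs)) stop("`fs` is required", call. = FALSE)
  tibble::tibble(
    beat_id = if ("beat_id" %in% names(beats)) beats$beat_id else seq_len(nrow(beats)),
    st = (beats$t_onset - beats$s_offset) / fs,
    pr = (beats$q_onset - beats$p_onset) / fs,
    qt = (beats$t_offset - beats$q_onset) / fs
  )
}
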