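# Independent brute-force oracles, kept deliberately naive: direct
# transcriptions of the defining formulas, no shared code with R/.

# double-loop bilateral filter with per-center adaptive sigmas
naive_bilateral <- function(x, params = filter_params(),
                            sigma_d = NULL, sigma_r = NULL) {
  n <- length(x)
  N <- params$half_width
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- max(1, i - N):min(n, i + N)
    vals <- x[idx]
    v <- mean((vals - mean(vals))^2)
    if (isTRUE(params$clamp_sigmas)) v <- min(v, params$sigma2_max)
    g <- log2(v / params$sigma2_max + 1)
    sd_d <- if (is.null(sigma_d)) g * params$sigma_d_max + params$sigma_min else sigma_d
    sd_r <- if (is.null(sigma_r)) g * params$sigma_r_max + params$sigma_min else sigma_r
    w <- 0
    acc <- 0
    for (j in idx) {
      wj <- exp(-(j - i)^2 / (2 * sd_d^2)) * exp(-(x[j] - x[i])^2 / (2 * sd_r^2))
      w <- w + wj
      acc <- acc + x[j] * wj
    }
    out[i] <- acc / w
  }
  out
}

# explicit loop moving sum with zero padding
naive_moving_sum <- function(d, n) {
  len <- length(d)
  vapply(seq_len(len), function(i) {
    sum(d[max(1, i - n):min(len, i + n)])
  }, numeric(1))
}

# strict local maxima of a numeric vector (interior points only)
local_maxima <- function(x) which(diff(sign(diff(x))) == -2) + 1L

# detection sensitivity/+P on one synthetic record
record_counts <- function(rec, fs = rec$fs, config = detector_config(fs)) {
  det <- ecg_detect(rec$record, fs = fs, config = config)
  match_annotations(det$beats$r_peak, rec$truth$r_peak, fs)
}
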