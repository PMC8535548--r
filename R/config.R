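#' Bilateral-filter parameters
#'
#' Parameters of the variance-adaptive one-dimensional bilateral filter used
#' as the ECG background predictor. The filter window holds `2 * half_width +
#' 1` samples; at 360 Hz the default half-width of 7 gives the 1 x 15 window
#' sized to the typical QRS duration (0.06--0.10 s).
#'
#' @param half_width Integer window half-width N (window spans `2N + 1`
#'   samples). Must be >= 1.
#' @param sigma_d_max Maximum standard deviation of the domain (spatial)
#'   Gaussian, reached when the local variance equals `sigma2_max`.
#' @param sigma_r_max Maximum standard deviation of the range (intensity)
#'   Gaussian.
#' @param sigma_min Floor added to both standard deviations so they never
#'   vanish on constant windows.
#' @param sigma2_max Reference variance of the normalized signal at which the
#'   adaptive standard deviations reach their maxima. The default 0.1310 was
#'   calibrated on normalized 360 Hz arrhythmia recordings.
#' @param clamp_sigmas If `TRUE`, local variance is clamped at `sigma2_max`
#'   before the log mapping so the standard deviations never exceed their
#'   maxima. Off by default: the mapping is applied as an open-ended formula.
#'
#' @return A list of class `"filter_params"`.
#' @seealso [bilateral_filter()], [adaptive_sigmas()]
#' @export
#' @examples
#' p <- filter_params()
#' adaptive_sigmas(0.1310, p)
filter_params <- function(half_width = 7,
                          sigma_d_max = 10,
                          sigma_r_max = 1,
                          sigma_min = 1e-5,
                          sigma2_max = 0.1310,
                          clamp_sigmas = FALSE) {
  stopifnot(
    half_width >= 1,
    sigma_d_max > 0, sigma_r_max > 0, sigma_min > 0, sigma2_max > 0,
    is.logical(clamp_sigmas)
  )
  structure(
    list(
      half_width = as.integer(half_width),
      sigma_d_max = sigma_d_max,
      sigma_r_max = sigma_r_max,
      sigma_min = sigma_min,
      sigma2_max = sigma2_max,
      clamp_sigmas = clamp_sigmas
    ),
    class = "filter_params"
  )
}

# rescale a sample count stated at 360 Hz to another sampling rate
scale_360 <- function(samples_at_360, fs) {
  max(1L, as.integer(round(fs * samples_at_360 / 360)))
}

#' Detector configuration
#'
#' Every tunable constant of the PQRST detector, resolved for a sampling
#' rate. Second-valued constants are converted to samples with
#' `round(seconds * fs)`; sample-valued constants stated at the 360 Hz
#' reference rate are rescaled proportionally, so 250 Hz records work
#' unchanged.
#'
#' @param fs Sampling rate in Hz.
#' @param filter [filter_params()] for the background predictor.
#' @param enhance_n Half-width (samples) of the moving sum that builds the
#'   enhanced residual; default 5 samples at 360 Hz, rescaled with `fs`.
#' @param min_run Minimum run length L of candidate samples for a run to be
#'   declared a candidate-R interval (default 8 at 360 Hz, rescaled).
#' @param thf Fragment threshold applied to the normalized rebound sum when
#'   accepting additional (fragmented) R-peaks.
#' @param qrs_sec,pr_sec,qt_sec Typical QRS, PR and QT durations in seconds;
#'   they size all search ranges.
#' @param alpha_qm Additional margin (samples at 360 Hz, rescaled) added to
#'   the Q-point search range.
#' @param rho_p,rho_t Acceptance ratios of the symmetric point filters for
#'   the P- and T-peak.
#' @param v_p_max,v_t_max Maximum deformation widths (samples skipped next to
#'   a wave apex) tried by the recursive point filters.
#' @param wing_p,wing_t Base wing lengths of the P and T point filters
#'   (samples at 360 Hz, rescaled); the effective wing is `wing - v`.
#' @param window_len,step Sliding-window length and step in samples (defaults
#'   2000 and 1600 at 360 Hz, rescaled).
#' @param tolerance_ms Matching tolerance used when stitching seam beats.
#' @param normalization `"minmax"` maps each window onto `[0, 1]`;
#'   `"literal"` divides the min-subtracted signal by the window maximum.
#'
#' @return A list of class `"detector_config"`, including the derived search
#'   ranges `alpha_f`, `alpha_q`, `alpha_ql`, `alpha_s`, `alpha_sr`,
#'   `alpha_p`, `alpha_t` (samples).
#' @export
#' @examples
#' cfg <- detector_config(fs = 360)
#' cfg$alpha_f   # 22 samples: half a typical QRS
detector_config <- function(fs = 360,
                            filter = filter_params(),
                            enhance_n = scale_360(5, fs),
                            min_run = scale_360(8, fs),
                            thf = 0.1,
                            qrs_sec = 0.12,
                            pr_sec = 0.2,
                            qt_sec = 0.44,
                            alpha_qm = scale_360(8, fs),
                            rho_p = 0.95,
                            rho_t = 0.95,
                            v_p_max = 5,
                            v_t_max = 10,
                            wing_p = scale_360(10, fs),
                            wing_t = scale_360(20, fs),
                            window_len = scale_360(2000, fs),
                            step = scale_360(1600, fs),
                            tolerance_ms = 50,
                            normalization = c("minmax", "literal")) {
  stopifnot(fs > 0, thf > 0, rho_p > 0, rho_p <= 1, rho_t > 0, rho_t <= 1)
  normalization <- match.arg(normalization)
  alpha_q <- as.integer(round(fs * qrs_sec / 2)) + as.integer(alpha_qm)
  cfg <- list(
    fs = fs,
    filter = filter,
    enhance_n = as.integer(enhance_n),
    min_run = as.integer(min_run),
    thf = thf,
    qrs_sec = qrs_sec,
    pr_sec = pr_sec,
    qt_sec = qt_sec,
    alpha_qm = as.integer(alpha_qm),
    alpha_f = as.integer(round(0.5 * fs * qrs_sec)),
    alpha_q = alpha_q,
    alpha_ql = as.integer(round(fs * qrs_sec)),
    alpha_s = alpha_q,
    alpha_sr = as.integer(round(fs * qrs_sec)),
    alpha_p = as.integer(round(fs * pr_sec)),
    alpha_t = as.integer(round(fs * (qt_sec - qrs_sec))),
    rho_p = rho_p,
    rho_t = rho_t,
    v_p_max = as.integer(v_p_max),
    v_t_max = as.integer(v_t_max),
    wing_p = as.integer(wing_p),
    wing_t = as.integer(wing_t),
    window_len = as.integer(window_len),
    step = as.integer(step),
    tolerance_ms = tolerance_ms,
    normalization = normalization
  )
  structure(cfg, class = "detector_config")
}

#' @export
print.detector_config <- function(x, ...) {
  cat("<detector_config> fs =", x$fs, "Hz\n")
  cat("  filter: N =", x$filter$half_width,
      " sigma_d_max =", x$filter$sigma_d_max,
      " sigma_r_max =", x$filter$sigma_r_max,
      " sigma2_max =", x$filter$sigma2_max, "\n")
  cat("  residual: enhance_n =", x$enhance_n, " min_run =", x$min_run,
      " thf =", x$thf, "\n")
  cat("  search ranges (samples): alpha_f =", x$alpha_f,
      " alpha_q =", x$alpha_q, " alpha_ql =", x$alpha_ql,
      " alpha_p =", x$alpha_p, " alpha_t =", x$alpha_t, "\n")
  cat("  windows:", x$window_len, "samples, step", x$step, "\n")
  invisible(x)
}
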