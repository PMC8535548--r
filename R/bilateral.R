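#' Population variance of a sample window
#'
#' Two-pass population variance (divide by the number of points, not n - 1)
#' of the values inside a filter window. Deterministic for tiny windows and
#' zero for constant ones.
#'
#' @param samples Non-empty numeric vector.
#' @return Non-negative scalar variance.
#' @export
#' @examples
#' local_variance(c(0, 1))  # 0.25
local_variance <- function(samples) {
  if (length(samples) == 0 || anyNA(samples)) {
    stop("`samples` must be a non-empty numeric vector without NA", call. = FALSE)
  }
  mean((samples - mean(samples))^2)
}

#' Variance-adaptive bilateral standard deviations
#'
#' Maps the local window variance onto the standard deviations of the domain
#' and range Gaussians:
#' \deqn{\sigma = \log_2(\sigma^2(\Omega)/\sigma^2_{max} + 1)\,\sigma_{max} + \sigma_{min}}
#' High-variance (QRS) windows therefore get strong smoothing while flat or
#' gently-sloped windows (baseline, P/T waves) are left nearly untouched.
#' Variance above `sigma2_max` passes through the same open-ended formula
#' unless `params$clamp_sigmas` is set.
#'
#' @param variance Non-negative variance(s) of the normalized signal.
#' @param params [filter_params()].
#' @return List with numeric elements `sigma_d` and `sigma_r`, both strictly
#'   positive and the same length as `variance`.
#' @export
#' @examples
#' adaptive_sigmas(0, filter_params())        # both collapse to sigma_min
#' adaptive_sigmas(0.1310, filter_params())   # log2(2) = 1: the maxima
adaptive_sigmas <- function(variance, params = filter_params()) {
  if (length(variance) == 0 || anyNA(variance) || any(variance < 0)) {
    stop("`variance` must be non-negative", call. = FALSE)
  }
  v <- if (isTRUE(params$clamp_sigmas)) pmin(variance, params$sigma2_max) else variance
  g <- log2(v / params$sigma2_max + 1)
  list(
    sigma_d = g * params$sigma_d_max + params$sigma_min,
    sigma_r = g * params$sigma_r_max + params$sigma_min
  )
}

#' One-dimensional bilateral filter (ECG background predictor)
#'
#' Edge-preserving nonlinear filter whose weight is the product of a spatial
#' Gaussian and an intensity Gaussian. With the variance-adaptive standard
#' deviations of [adaptive_sigmas()] it suppresses the narrow high-variance
#' QRS interval while restoring the P/T waves and flat baseline, so its
#' output is the predicted background signal and the residual `I - B`
#' isolates the QRS.
#'
#' The window is truncated at the signal edges and the weights renormalized
#' over the available points, so every output value is a convex combination
#' of the input values inside its window. Constant signals are fixed points.
#'
#' @param signal Numeric vector (normally a normalized window in `[0, 1]`).
#' @param params [filter_params()].
#' @param sigma_d,sigma_r Optional fixed standard deviations that bypass the
#'   adaptive schedule (scalar or one value per sample); used for controlled
#'   experiments and tests.
#' @return Numeric vector of the same length: the predicted background.
#' @export
#' @examples
#' bilateral_filter(rep(0.4, 20))              # constant in, constant out
#' x <- sin(seq(0, pi, length.out = 50))
#' b <- bilateral_filter(x)
bilateral_filter <- function(signal, params = filter_params(),
                             sigma_d = NULL, sigma_r = NULL) {
  n <- length(signal)
  if (n < 1 || anyNA(signal)) {
    stop("`signal` must be a non-empty numeric vector without NA", call. = FALSE)
  }
  N <- params$half_width
  offsets <- -N:N
  k <- length(offsets)

  idx <- outer(seq_len(n), offsets, `+`)          # n x k neighbor indices
  valid <- idx >= 1L & idx <= n
  idx_safe <- ifelse(valid, idx, 1L)
  M <- matrix(signal[idx_safe], nrow = n, ncol = k)
  M[!valid] <- NA_real_

  counts <- rowSums(valid)
  mu <- rowSums(M, na.rm = TRUE) / counts
  v <- rowSums(M^2, na.rm = TRUE) / counts - mu^2
  v <- pmax(v, 0)                                 # guard round-off

  if (is.null(sigma_d) || is.null(sigma_r)) {
    sig <- adaptive_sigmas(v, params)
    sd_d <- if (is.null(sigma_d)) sig$sigma_d else rep_len(sigma_d, n)
    sd_r <- if (is.null(sigma_r)) sig$sigma_r else rep_len(sigma_r, n)
  } else {
    sd_d <- rep_len(sigma_d, n)
    sd_r <- rep_len(sigma_r, n)
  }

  dist2 <- matrix(offsets^2, nrow = n, ncol = k, byrow = TRUE)
  w_dom <- exp(-dist2 / (2 * sd_d^2))
  w_rng <- exp(-(M - signal)^2 / (2 * sd_r^2))
  w <- w_dom * w_rng
  w[!valid] <- 0
  Mw <- M
  Mw[!valid] <- 0
  rowSums(Mw * w) / rowSums(w)
}
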