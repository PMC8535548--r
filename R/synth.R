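#' Specification of one synthetic beat
#'
#' Each wave component is a truncated Gaussian bump: the raw Gaussian is
#' shifted down by 1% of its amplitude and clipped at zero, so the
#' component's support is exactly finite and the true onset/offset are the
#' first and last nonzero samples. Apexes are therefore analytically known,
#' which is what makes the generator a ground-truth substrate.
#'
#' Default timings follow textbook morphology (P-wave about 0.09 s wide
#' ending about 0.05 s before the QRS, QRS about 0.08 s, T-wave about
#' 0.16 s wide centered 0.25 s after R), with amplitudes in millivolts.
#'
#' @param p_amp,q_amp,r_amp,s_amp,t_amp Component amplitudes (mV, signed).
#' @param p_center,q_center,s_center,t_center Component centers relative to
#'   the R apex (seconds); R sits at `r_offset_sec` into the beat.
#' @param p_width,q_width,r_width,s_width,t_width Gaussian standard
#'   deviations (seconds).
#' @param r_polarity +1 or -1; -1 negates the whole QRS (PVC-like beat).
#' @param fragment_pattern `"none"`, `"fR-L"`, `"fR-R"`, `"fR-L2"`,
#'   `"fR-R2"` (notched R-waves with one or two secondary bumps), or
#'   `"flat"` (flat-topped R).
#' @param fragment_amp Amplitude of each secondary notch bump (mV).
#' @param t_shape `"normal"`, `"inverted"`, `"biphasic"`, `"hyperacute"` or
#'   `"plateau"`.
#' @param t_plateau_v Half-width (samples) of the flattened apex when
#'   `t_shape = "plateau"` (the plateau spans `2 * v + 1` samples).
#' @param p_present If `FALSE` the P-wave is omitted (flat PR region).
#' @param p_inverted If `TRUE` the P-wave is negated.
#' @param rr_interval Beat length in seconds.
#' @param r_offset_sec Position of the R apex inside the beat (seconds).
#' @return A list of class `"beat_spec"`.
#' @export
beat_spec <- function(p_amp = 0.15, q_amp = -0.10, r_amp = 1.0,
                      s_amp = -0.15, t_amp = 0.30,
                      p_center = -0.170, q_center = -0.030,
                      s_center = 0.035, t_center = 0.250,
                      p_width = 0.015, q_width = 0.008, r_width = 0.016,
                      s_width = 0.008, t_width = 0.026,
                      r_polarity = 1L,
                      fragment_pattern = c("none", "fR-L", "fR-R",
                                           "fR-L2", "fR-R2", "flat"),
                      fragment_amp = 0.30,
                      t_shape = c("normal", "inverted", "biphasic",
                                  "hyperacute", "plateau"),
                      t_plateau_v = 2L,
                      p_present = TRUE,
                      p_inverted = FALSE,
                      rr_interval = 0.8,
                      r_offset_sec = 0.25) {
  fragment_pattern <- match.arg(fragment_pattern)
  t_shape <- match.arg(t_shape)
  stopifnot(
    rr_interval > 0, r_offset_sec > 0, r_polarity %in% c(-1L, 1L),
    all(c(p_width, q_width, r_width, s_width, t_width) > 0)
  )
  structure(as.list(environment()), class = "beat_spec")
}

# truncated Gaussian bump: exactly zero outside +/- sqrt(2 log(100)) sd
bump <- function(t, center, amp, sd) {
  g <- exp(-(t - center)^2 / (2 * sd^2))
  amp * pmax(0, (g - 0.01) / 0.99)
}

bump_halfwidth <- function(sd) sqrt(2 * log(100)) * sd  # ~3.035 sd

#' Synthesize one beat with exact ground-truth fiducials
#'
#' @param spec [beat_spec()].
#' @param fs Sampling rate in Hz.
#' @return List with `samples` (numeric, length `round(rr_interval * fs)`)
#'   and `truth`, a one-row tibble with the 11 true fiducial indices
#'   (1-based within the beat), `gamma`, `omega_p`, `omega_t` and the list
#'   columns `frag_left`/`frag_right` of true additional-peak indices.
#' @export
#' @examples
#' b <- synthesize_beat(beat_spec(), fs = 360)
#' b$truth$r_peak
synthesize_beat <- function(spec, fs) {
  n <- round(spec$rr_interval * fs)
  r0 <- spec$r_offset_sec
  t <- (seq_len(n) - 1) / fs - r0          # time relative to the R apex

  t_amp <- switch(spec$t_shape,
    normal = spec$t_amp, hyperacute = 2.5 * spec$t_amp,
    inverted = -abs(spec$t_amp), biphasic = spec$t_amp,
    plateau = spec$t_amp
  )
  comp <- list(
    p = if (spec$p_present) {
      bump(t, spec$p_center, (if (spec$p_inverted) -1 else 1) * spec$p_amp,
           spec$p_width)
    } else {
      numeric(n)
    },
    q = bump(t, spec$q_center, spec$q_amp, spec$q_width),
    r = bump(t, 0, spec$r_amp, spec$r_width),
    s = bump(t, spec$s_center, spec$s_amp, spec$s_width),
    t = bump(t, spec$t_center, t_amp, spec$t_width)
  )
  if (spec$t_shape == "biphasic") {
    comp$t <- comp$t + bump(t, spec$t_center + 3.2 * spec$t_width,
                            -0.6 * spec$t_amp, 0.7 * spec$t_width)
  }

  frag_left <- numeric(0)
  frag_right <- numeric(0)
  notch_sd <- 0.006
  notch_gap <- 0.036
  if (spec$fragment_pattern %in% c("fR-R", "fR-R2")) {
    frag_right <- notch_gap
    if (spec$fragment_pattern == "fR-R2") frag_right <- c(notch_gap, 2 * notch_gap)
  }
  if (spec$fragment_pattern %in% c("fR-L", "fR-L2")) {
    frag_left <- -notch_gap
    if (spec$fragment_pattern == "fR-L2") frag_left <- c(-notch_gap, -2 * notch_gap)
  }
  for (fc in c(frag_left, frag_right)) {
    comp$r <- comp$r + bump(t, fc, spec$fragment_amp, notch_sd)
  }

  qrs <- comp$q + comp$r + comp$s
  if (spec$r_polarity < 0) qrs <- -qrs
  samples <- comp$p + qrs + comp$t

  r_idx <- which.min(abs(t))               # sample at the R apex
  if (spec$fragment_pattern == "flat") {
    k <- 2L
    plat <- (r_idx - k):(r_idx + k)
    samples[plat] <- samples[r_idx]
  }
  if (spec$t_shape == "plateau") {
    t_idx <- which.min(abs(t - spec$t_center))
    v <- spec$t_plateau_v
    plat <- (t_idx - v):(t_idx + v)
    samples[plat] <- samples[t_idx]
  }

  support <- function(x) {
    nz <- which(abs(x) > 0)
    if (!length(nz)) c(NA_integer_, NA_integer_) else range(nz)
  }
  apex <- function(x, sign = 1) which.max(sign * x)
  p_rng <- support(comp$p)
  q_rng <- support(comp$q)
  s_rng <- support(comp$s)
  t_rng <- support(comp$t)

  frag_idx <- function(centers) {
    vapply(centers, function(fc) which.min(abs(t - fc)), integer(1))
  }
  gamma <- as.integer(spec$r_polarity)
  omega_t <- if (spec$t_shape == "inverted") -1L else 1L
  omega_p <- if (spec$p_present && spec$p_inverted) -1L else 1L
  t_apex_sign <- if (omega_t < 0) -1 else 1

  truth <- tibble::tibble(
    p_onset = if (spec$p_present) p_rng[1] else q_rng[1],
    p_peak = if (spec$p_present) apex(comp$p, if (spec$p_inverted) -1 else 1) else q_rng[1],
    p_offset = if (spec$p_present) p_rng[2] else q_rng[1],
    q_onset = q_rng[1],
    q_peak = apex(comp$q, -1) * 1L,
    r_peak = r_idx,
    s_peak = apex(comp$s, -1) * 1L,
    s_offset = s_rng[2],
    t_onset = t_rng[1],
    t_peak = apex(comp$t, t_apex_sign),
    t_offset = t_rng[2],
    gamma = gamma,
    omega_p = omega_p,
    omega_t = omega_t,
    frag_left = list(frag_idx(frag_left)),
    frag_right = list(frag_idx(frag_right)),
    p_present = spec$p_present
  )
  if (!all(diff(as.numeric(truth[1, fiducial_cols])) >= 0)) {
    stop("invalid spec: components overlap and violate fiducial ordering",
         call. = FALSE)
  }
  list(samples = samples, truth = truth)
}

#' Synthesize a multi-beat ECG record with ground truth
#'
#' Concatenates beats (optionally with jittered RR intervals), then adds
#' optional baseline wander and white Gaussian noise at a stated SNR,
#' defined as `10 * log10(signal power / noise power)` over the whole
#' record. Fully reproducible for a given seed.
#'
#' @param spec [beat_spec()] shared by all beats (the `rr_interval` field is
#'   the mean RR).
#' @param n_beats Number of beats (>= 1).
#' @param rr_jitter Standard deviation (s) of Gaussian jitter applied to
#'   each beat's RR interval; 0 disables jitter.
#' @param fs Sampling rate in Hz.
#' @param snr_db Target signal-to-noise ratio in dB, or `NULL` for a
#'   noise-free record.
#' @param baseline_amp,baseline_freq Amplitude (mV) and frequency (Hz) of a
#'   sinusoidal baseline wander; amplitude 0 disables it.
#' @param seed Integer seed; generation is bit-reproducible.
#' @param noise Optional pre-generated standard-normal vector recycled as
#'   the noise source (scaled to the requested SNR); lets callers compare
#'   SNR levels against the identical noise realization.
#' @return List with `record` (tibble `sample`, `mv`), `truth` (tibble of
#'   per-beat true fiducials, indices absolute and 1-based), `fs`, `clean`
#'   (noise-free samples) and `noise` (the added noise, possibly zero).
#' @export
#' @examples
#' rec <- synthesize_record(n_beats = 5, seed = 42)
#' nrow(rec$truth)
synthesize_record <- function(spec = beat_spec(), n_beats = 30,
                              rr_jitter = 0, fs = 360, snr_db = NULL,
                              baseline_amp = 0, baseline_freq = 0.3,
                              seed = NULL, noise = NULL) {
  stopifnot(n_beats >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))

  rrs <- rep(spec$rr_interval, n_beats)
  if (rr_jitter > 0) {
    rrs <- rrs + stats::rnorm(n_beats, 0, rr_jitter)
    rrs <- pmax(rrs, spec$rr_interval * 0.6)
  }

  pieces <- vector("list", n_beats)
  truths <- vector("list", n_beats)
  offset <- 0L
  for (b in seq_len(n_beats)) {
    sp <- spec
    sp$rr_interval <- rrs[b]
    one <- synthesize_beat(sp, fs)
    tr <- one$truth
    for (col in fiducial_cols) tr[[col]] <- tr[[col]] + offset
    tr$frag_left <- list(tr$frag_left[[1]] + offset)
    tr$frag_right <- list(tr$frag_right[[1]] + offset)
    tr$beat_id <- b
    pieces[[b]] <- one$samples
    truths[[b]] <- tr
    offset <- offset + length(one$samples)
  }
  clean <- unlist(pieces, use.names = FALSE)
  n <- length(clean)

  if (baseline_amp > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    clean_bw <- clean + baseline_amp *
      sin(2 * pi * baseline_freq * (seq_len(n) - 1) / fs + phase)
  } else {
    clean_bw <- clean
  }

  added <- numeric(n)
  if (!is.null(snr_db)) {
    p_sig <- mean(clean_bw^2)
    sd_n <- sqrt(p_sig / 10^(snr_db / 10))
    z <- if (is.null(noise)) stats::rnorm(n) else rep_len(noise, n)
    added <- sd_n * z
  }
  mv <- clean_bw + added

  list(
    record = tibble::tibble(sample = seq_len(n), mv = mv),
    truth = dplyr::bind_rows(truths),
    fs = fs,
    clean = clean_bw,
    noise = added
  )
}
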