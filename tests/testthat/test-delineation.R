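# Constructed-waveform tests: each beat is generated with analytically known
# fiducials (truncated Gaussian components), so the expected indices are the
# generator's ground truth, not values echoed from the detector.

fid_cols <- c("p_onset", "p_peak", "p_offset", "q_onset", "q_peak", "r_peak",
              "s_peak", "s_offset", "t_onset", "t_peak", "t_offset")

test_that("Q and S notches and their shoulders are found on planted beats", {
  cfg <- detector_config(360)
  rec <- synthesize_record(n_beats = 4, seed = 1)
  I <- normalize_window(rec$record$mv)
  tr <- rec$truth[2, ]

  q <- detect_q(I, tr$r_peak, 1L, cfg)
  expect_false(q$mapped)
  expect_lte(abs(q$index - tr$q_peak), 3)

  q_on <- detect_q_onset(I, q$index, 1L, cfg)
  expect_false(q_on$mapped)
  expect_lte(abs(q_on$index - tr$q_onset), 2)

  s <- detect_s(I, tr$r_peak, 1L, cfg)
  expect_false(s$mapped)
  expect_lte(abs(s$index - tr$s_peak), 3)

  s_off <- detect_s_offset(I, s$index, 1L, cfg)
  expect_false(s_off$mapped)
  expect_lte(abs(s_off$index - tr$s_offset), 2)
})

test_that("a monotone flank with no notch maps Q to the range end", {
  cfg <- detector_config(360)
  # pure R bump: no Q notch anywhere left of R
  x <- pqrst:::bump((0:299) / 360 - 0.4, 0, 1, 0.02) + 0.001 * (0:299) / 360
  I <- list(samples = x, mean_value = mean(x))
  r <- which.max(x)
  q <- detect_q(I, r, 1L, cfg)
  expect_true(q$mapped)
  expect_equal(q$index, max(r - cfg$alpha_q, 2L))
})

test_that("Q/S detection mirrors under beat inversion", {
  cfg <- detector_config(360)
  rec <- synthesize_record(n_beats = 4, seed = 1)
  I <- normalize_window(rec$record$mv)
  tr <- rec$truth[2, ]
  q_up <- detect_q(I, tr$r_peak, 1L, cfg)

  inv <- normalize_window(-rec$record$mv)
  q_dn <- detect_q(inv, tr$r_peak, -1L, cfg)
  expect_equal(q_dn$index, q_up$index)
})

test_that("symmetric point filter finds apexes of both polarities", {
  # symmetric bump on a flat-but-structured background inside the range
  t <- (0:999) / 360
  b <- pqrst:::bump(t, 1.5, 0.3, 0.03)
  apex <- which.max(b)

  up <- detect_wave_peak(b, from = apex + 150L, direction = "left",
                         range_len = 300L, omega = 1L, wing = 10L,
                         v_max = 5L, rho = 0.95)
  expect_equal(up$index, apex)
  expect_equal(up$v_true, 0L)

  dn <- detect_wave_peak(-b, from = apex + 150L, direction = "left",
                         range_len = 300L, omega = -1L, wing = 10L,
                         v_max = 5L, rho = 0.95)
  expect_equal(dn$index, apex)

  # no candidate of the wrong polarity on a clean bump
  expect_null(detect_wave_peak(b, from = apex + 150L, direction = "left",
                               range_len = 300L, omega = -1L, wing = 10L,
                               v_max = 5L, rho = 0.95))
})

test_that("plateaued apexes are accepted inside the apex region at minimal v", {
  t <- (0:999) / 360
  b <- pqrst:::bump(t, 1.5, 0.3, 0.03)
  apex <- which.max(b)
  v_plat <- 2L
  b[(apex - v_plat):(apex + v_plat)] <- b[apex]

  got <- detect_wave_peak(b, from = apex + 150L, direction = "left",
                          range_len = 300L, omega = 1L, wing = 20L,
                          v_max = 10L, rho = 0.95)
  expect_false(is.null(got))
  expect_lte(abs(got$index - apex), v_plat + 2L)

  # v_true is minimal: exhaustive search over v with the same predicate
  s <- sign(b[-length(b)] - b[-1])
  fires_at_v <- function(v) {
    lw <- 20L - v
    any(vapply((apex - 40L):(apex + 40L), function(x0) {
      pqrst:::peak_filter_fires(s, x0, 1L, v, lw, lw, 0.95)
    }, logical(1)))
  }
  v_min <- which(vapply(0:10, fires_at_v, logical(1)))[1] - 1L
  expect_equal(got$v_true, v_min)
})

test_that("asymmetric bound filter stops exactly at planted toes", {
  t <- (0:999) / 360
  b <- pqrst:::bump(t, 1.5, 0.3, 0.03)
  apex <- which.max(b)
  toe_l <- min(which(b > 0)) - 1L   # last zero sample before the bump
  toe_r <- max(which(b > 0)) + 1L

  on <- detect_wave_bounds(b, apex, 1L, 0L, "onset",
                           lower = apex - 150L, upper = apex)
  off <- detect_wave_bounds(b, apex, 1L, 0L, "offset",
                            lower = apex, upper = apex + 150L)
  expect_lte(abs(on - toe_l), 1)
  expect_lte(abs(off - toe_r), 1)

  # inverted bump: mirrored toes with omega = -1
  on_i <- detect_wave_bounds(-b, apex, -1L, 0L, "onset",
                             lower = apex - 150L, upper = apex)
  expect_equal(on_i, on)

  # truncation at the range boundary yields no bound
  expect_null(detect_wave_bounds(b, apex, 1L, 0L, "onset",
                                 lower = apex - 3L, upper = apex))
})

test_that("polarity selection needs both larger width and larger area", {
  b <- c(rep(0, 10), 0.1, 0.3, 0.1, rep(0, 10), -0.2, -0.5, -0.8, -0.5, -0.2,
         rep(0, 10))
  narrow_up <- list(onset = 10, peak = 12, offset = 14, omega = 1L, v_true = 0L)
  wide_dn <- list(onset = 23, peak = 26, offset = 29, omega = -1L, v_true = 0L)
  expect_equal(select_wave_polarity(narrow_up, wide_dn, b)$omega, -1L)

  # inverted wider but smaller area: conjunction fails, normal wins
  tall_up <- list(onset = 10, peak = 12, offset = 14, omega = 1L, v_true = 0L)
  b2 <- c(rep(0, 10), 0.1, 2.0, 0.1, rep(0, 10), -0.05, -0.1, -0.12, -0.1,
          -0.05, rep(0, 10))
  shallow_dn <- list(onset = 23, peak = 26, offset = 29, omega = -1L,
                     v_true = 0L)
  expect_equal(select_wave_polarity(tall_up, shallow_dn, b2)$omega, 1L)

  expect_equal(select_wave_polarity(narrow_up, NULL, b)$omega, 1L)
  expect_null(select_wave_polarity(NULL, NULL, b))
})

test_that("mapping guarantees totality and the ordering invariant", {
  beat <- list(q_onset = 100L, s_offset = 140L, p_peak = NULL, p_onset = NULL,
               p_offset = NULL, t_peak = NULL, t_onset = NULL, t_offset = NULL)
  m <- map_missing_fps(beat)
  expect_equal(m$p_onset, 100L)
  expect_equal(m$p_peak, 100L)
  expect_equal(m$p_offset, 100L)
  expect_equal(m$t_onset, 140L)
  expect_setequal(m$mapped, c("p_onset", "p_peak", "p_offset",
                              "t_onset", "t_peak", "t_offset"))

  # fully detected beat: identity
  full <- list(q_onset = 100L, s_offset = 140L, p_onset = 60L, p_peak = 70L,
               p_offset = 80L, t_onset = 180L, t_peak = 200L, t_offset = 220L)
  f <- map_missing_fps(full)
  expect_length(f$mapped, 0)
  expect_equal(f$p_onset, 60L)

  # T-peak found but offset not: offset maps to the peak
  part <- list(q_onset = 100L, s_offset = 140L, p_onset = 60L, p_peak = 70L,
               p_offset = 80L, t_onset = 180L, t_peak = 200L, t_offset = NULL)
  p <- map_missing_fps(part)
  expect_equal(p$t_offset, 200L)
  expect_equal(p$mapped, "t_offset")
})

test_that("time-reversing a symmetric beat swaps onset/offset and Q/S roles", {
  sp <- beat_spec(p_amp = 0.3, t_amp = 0.3, p_center = -0.25, t_center = 0.25,
                  p_width = 0.026, t_width = 0.026, q_amp = -0.15,
                  s_amp = -0.15, q_center = -0.035, s_center = 0.035,
                  q_width = 0.008, s_width = 0.008, r_offset_sec = 0.4)
  rec <- synthesize_record(sp, n_beats = 5, seed = 1)
  L <- nrow(rec$record)
  bf <- ecg_detect(rec$record, fs = 360)$beats
  br <- ecg_detect(rev(rec$record$mv), fs = 360)$beats
  br <- br[rev(seq_len(nrow(br))), ]
  refl <- function(i) L + 1L - i

  expect_equal(bf$r_peak, refl(br$r_peak))
  expect_equal(bf$q_peak, refl(br$s_peak))
  expect_equal(bf$s_peak, refl(br$q_peak))
  expect_equal(bf$q_onset, refl(br$s_offset))
  expect_equal(bf$p_peak, refl(br$t_peak))
  expect_equal(bf$p_onset, refl(br$t_offset))
  expect_equal(bf$p_offset, refl(br$t_onset))
  expect_equal(bf$t_onset, refl(br$p_offset))
  expect_equal(bf$t_offset, refl(br$p_onset))
})

test_that("full-pipeline delineation recovers planted fiducials", {
  rec <- synthesize_record(n_beats = 10, seed = 9)
  det <- ecg_detect(rec$record, fs = 360)
  expect_equal(nrow(det$beats), 10)

  err <- abs(as.matrix(det$beats[, fid_cols]) - as.matrix(rec$truth[, fid_cols]))
  expect_lte(max(err[, c("p_peak", "t_peak", "r_peak")]), 1)
  expect_lte(max(err[, c("p_onset", "p_offset", "t_onset", "t_offset")]), 3)

  # ordering invariant on every detected beat
  for (i in seq_len(nrow(det$beats))) {
    expect_true(all(diff(as.numeric(det$beats[i, fid_cols])) >= 0))
  }
})
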