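test_that("window normalization maps onto [0,1] and records the mean", {
  nw <- normalize_window(c(0, 5, 10))
  expect_equal(nw$samples, c(0, 0.5, 1))
  expect_equal(normalize_window(c(-1, 0, 1))$samples, c(0, 0.5, 1))
  expect_equal(nw$mean_value, 0.5)

  # literal mode divides by the raw maximum
  expect_equal(normalize_window(c(2, 4), mode = "literal")$samples, c(0, 0.5))

  expect_error(normalize_window(rep(3, 10)), "degenerate")
})

test_that("enhanced residual is the zero-padded moving sum", {
  expect_equal(enhance_residual(c(0, 0, 1, 0, 0), 1), c(0, 1, 1, 1, 0))
  d <- c(3, -1, 2)
  expect_equal(enhance_residual(d, 0), d)

  set.seed(5)
  d <- rnorm(100)
  expect_equal(enhance_residual(d, 5), naive_moving_sum(d, 5))
})

test_that("candidate runs respect the minimum run length", {
  E <- c(rep(0, 10), rep(1, 7), rep(0, 10))
  expect_length(candidate_r_intervals(E, threshold = 0.5, min_run = 8), 0)

  E8 <- c(rep(0, 10), rep(1, 8), rep(0, 10))
  runs <- candidate_r_intervals(E8, threshold = 0.5, min_run = 8)
  expect_length(runs, 1)
  expect_equal(runs[[1]], 11:18)

  expect_length(candidate_r_intervals(rep(0.1, 30), threshold = 0.5), 0)

  # magnitude thresholding: a negative lobe forms a run too
  En <- c(rep(0, 10), rep(-1, 9), rep(0, 10))
  expect_length(candidate_r_intervals(En, threshold = 0.5, min_run = 8), 1)
})

test_that("R-peak polarity and flat-top ties resolve as specified", {
  I <- list(samples = c(0.1, 0.9, 0.5), mean_value = 0.2)
  r <- locate_r_peak(I, 1:3)
  expect_equal(r$index, 2L)
  expect_equal(r$gamma, 1L)
  expect_false(r$is_flat)

  I2 <- list(samples = c(0.5, 0.1, 0.5), mean_value = 0.6)
  r2 <- locate_r_peak(I2, 1:3)
  expect_equal(r2$index, 2L)
  expect_equal(r2$gamma, -1L)

  # equal maxima at positions 5 and 7 -> average position 6, flat flag
  x <- c(0.1, 0.1, 0.2, 0.3, 0.8, 0.5, 0.8, 0.3, 0.1)
  I3 <- list(samples = x, mean_value = 0.3)
  r3 <- locate_r_peak(I3, 1:9)
  expect_equal(r3$index, 6L)
  expect_true(r3$is_flat)

  # tie at 4 and 5 -> floor of 4.5
  x4 <- c(0.1, 0.2, 0.3, 0.8, 0.8, 0.3)
  r4 <- locate_r_peak(list(samples = x4, mean_value = 0.3), 1:6)
  expect_equal(r4$index, 4L)
})

test_that("additional R-peaks: clean flanks give none, planted notches fire", {
  cfg <- detector_config(360)
  rec <- synthesize_record(n_beats = 4, seed = 2)
  I <- normalize_window(rec$record$mv)
  tr <- rec$truth[2, ]
  r <- list(index = tr$r_peak, gamma = 1L)
  expect_length(detect_additional_r(I, r, "right", cfg), 0)
  expect_length(detect_additional_r(I, r, "left", cfg), 0)

  # planted fR-R notch recovered near its true position
  recf <- synthesize_record(beat_spec(fragment_pattern = "fR-R"),
                            n_beats = 4, seed = 2)
  If <- normalize_window(recf$record$mv)
  trf <- recf$truth[2, ]
  rf <- list(index = trf$r_peak, gamma = 1L)
  add <- detect_additional_r(If, rf, "right", cfg)
  expect_length(add, 1)
  expect_lte(abs(add - trf$frag_right[[1]]), 2)

  # two left notches found by recursion, in scan order
  rec2 <- synthesize_record(beat_spec(fragment_pattern = "fR-L2"),
                            n_beats = 4, seed = 2)
  I2 <- normalize_window(rec2$record$mv)
  tr2 <- rec2$truth[2, ]
  add2 <- detect_additional_r(I2, list(index = tr2$r_peak, gamma = 1L),
                              "left", cfg)
  expect_length(add2, 2)
  expect_true(all(abs(sort(add2) - sort(tr2$frag_left[[1]])) <= 2))

  # raising the threshold above the rebound silences detection
  cfg_hi <- detector_config(360, thf = 10)
  expect_length(detect_additional_r(If, rf, "right", cfg_hi), 0)
})

test_that("detected indices are invariant to positive gain", {
  rec <- synthesize_record(n_beats = 6, seed = 3)
  d1 <- ecg_detect(rec$record$mv, fs = 360)
  d2 <- ecg_detect(rec$record$mv * 12.5, fs = 360)
  d3 <- ecg_detect(rec$record$mv * 0.2, fs = 360)
  expect_identical(d1$beats$r_peak, d2$beats$r_peak)
  expect_identical(d1$beats$r_peak, d3$beats$r_peak)
  expect_identical(d1$beats$t_onset, d2$beats$t_onset)
  expect_identical(d1$beats$p_onset, d3$beats$p_onset)
})

test_that("inverting a record flips gamma and keeps R positions", {
  rec <- synthesize_record(n_beats = 6, seed = 4)
  d1 <- ecg_detect(rec$record$mv, fs = 360)
  d2 <- ecg_detect(2 * mean(rec$record$mv) - rec$record$mv, fs = 360)
  expect_equal(nrow(d1$beats), nrow(d2$beats))
  expect_true(all(d1$beats$gamma == 1L))
  expect_true(all(d2$beats$gamma == -1L))
  expect_true(all(abs(d1$beats$r_peak - d2$beats$r_peak) <= 1))
})

test_that("clean multi-window records are recovered perfectly", {
  rec <- synthesize_record(n_beats = 30, rr_jitter = 0.05, seed = 7)
  det <- ecg_detect(rec$record, fs = rec$fs)
  m <- match_annotations(det$beats$r_peak, rec$truth$r_peak, rec$fs)
  expect_equal(m$tp, 30L)
  expect_equal(m$fn, 0L)
  expect_equal(m$fp, 0L)
})
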