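test_that("time-domain metrics match closed forms", {
  m <- hrv_time(c(0.800, 0.860, 0.800, 0.860))
  expect_equal(m$nn50, 3)
  expect_equal(m$pnn50, 100)
  expect_equal(m$rmssd, 60, tolerance = 1e-9)

  mc <- hrv_time(rep(0.8, 50))
  expect_equal(mc$rmssd, 0)
  expect_equal(mc$nn50, 0)
  expect_equal(mc$hti, 1)     # single occupied histogram bin
  expect_equal(mc$tinn, 0)
  expect_equal(mc$hr_mean, 75)

  expect_error(hrv_time(0.8), "insufficient")
})

test_that("time-domain metrics agree with direct formula evaluation", {
  set.seed(21)
  x <- 0.8 + 0.1 * rnorm(300)
  m <- hrv_time(x)
  d <- diff(x)
  expect_equal(m$rr_mean, mean(x))
  expect_equal(m$rr_std, sd(x))
  expect_equal(m$hr_mean, mean(60 / x))
  expect_equal(m$hr_std, sd(60 / x))
  expect_equal(m$nn50, sum(abs(d) > 0.05))
  expect_equal(m$pnn50, 100 * sum(abs(d) > 0.05) / (length(x) - 1))
  expect_equal(m$rmssd, sqrt(mean(d^2)) * 1000)
  # pNN50 normalization identity and hr/rr consistency
  expect_equal(m$pnn50, 100 * m$nn50 / (length(x) - 1))
  expect_equal(mean(60 / x), m$hr_mean, tolerance = 1e-9)
})

test_that("single tachogram tones land in their spectral bands", {
  mk <- function(f) {
    tt <- seq(0.8, 300, by = 0.8)
    tibble::tibble(interval = 0.8 + 0.05 * sin(2 * pi * f * tt), time = tt)
  }
  hf <- hrv_freq(mk(0.25))
  expect_gt(hf$hf_norm, 90)

  lf <- hrv_freq(mk(0.10))
  expect_gt(lf$lf_norm, 90)

  # constant tachogram: all powers vanish, normalized values undefined
  const <- tibble::tibble(interval = rep(0.8, 400),
                          time = cumsum(rep(0.8, 400)))
  fc <- hrv_freq(const)
  expect_lt(fc$vlf_power + fc$lf_power + fc$hf_power, 1e-12)
  expect_true(is.na(fc$lf_hf_ratio))
})

test_that("band powers are non-negative and percentages bounded", {
  set.seed(31)
  n <- 350
  x <- 0.8 + 0.05 * rnorm(n)
  rr <- tibble::tibble(interval = x, time = cumsum(x))
  f <- hrv_freq(rr)
  expect_gte(f$vlf_power, 0)
  expect_gte(f$lf_power, 0)
  expect_gte(f$hf_power, 0)
  expect_lte(f$vlf_pct + f$lf_pct + f$hf_pct, 100 + 1e-9)
  f2 <- hrv_freq(rr, method = "direct")
  expect_gte(f2$hf_power, 0)
})

test_that("interval trends are plain fiducial arithmetic", {
  beats <- tibble::tibble(
    beat_id = 1:2,
    p_onset = c(20L, 320L), q_onset = c(50L, 350L),
    s_offset = c(100L, 400L), t_onset = c(136L, 436L),
    t_offset = c(208L, 508L)
  )
  tr <- interval_trends(beats, fs = 360)
  expect_equal(tr$st, c(0.1, 0.1))
  expect_equal(tr$pr, c(30, 30) / 360)
  expect_equal(tr$qt[1], 158 / 360)   # ~0.439 s

  # fully mapped P: PR collapses to zero
  mapped <- tibble::tibble(p_onset = 50L, q_onset = 50L, s_offset = 90L,
                           t_onset = 120L, t_offset = 180L)
  expect_equal(interval_trends(mapped, fs = 360)$pr, 0)
})

test_that("rr_intervals works from detections, tables and vectors", {
  rr <- rr_intervals(c(100, 460, 820), fs = 360)
  expect_equal(rr$interval, c(1, 1))
  expect_equal(rr$time, c(460, 820) / 360)

  rec <- synthesize_record(n_beats = 6, seed = 5)
  det <- ecg_detect(rec$record, fs = 360)
  rr2 <- rr_intervals(det)
  expect_equal(nrow(rr2), 5)
  expect_true(all(rr2$interval > 0))
})
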