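test_that("segment QC applies the dropped-frame, duration and occlusion rules", {
  # 15 s at 30 fps, clean
  s <- landmark_series(make_landmark_df(450), fps = 30)
  r <- qc_segment(s)
  expect_true(r$pass)
  expect_equal(r$continuous_duration_s, 15)
  expect_equal(r$occlusion_runs, 0)

  # 6% dropped (at the tail so continuity is preserved) fails the >5% rule
  s6 <- landmark_series(make_landmark_df(900, drop_frames = 846:899), fps = 30)
  r6 <- qc_segment(s6)
  expect_false(r6$pass)
  expect_true("dropped_frames" %in% r6$reasons)

  # exactly 5% passes: the rule is strictly greater-than
  s5 <- landmark_series(make_landmark_df(1000, drop_frames = 950:999), fps = 30)
  expect_false("dropped_frames" %in% qc_segment(s5, min_duration_s = 10)$reasons)

  # 14.9 s clean fails on duration alone
  s14 <- landmark_series(make_landmark_df(447), fps = 30)
  r14 <- qc_segment(s14)
  expect_false(r14$pass)
  expect_equal(r14$reasons, "duration")

  # occluded frames (confidence below threshold) create occlusion runs
  dfo <- make_landmark_df(500)
  dfo$confidence[dfo$frame %in% 100:104] <- 0.01
  ro <- qc_segment(landmark_series(dfo, fps = 30), min_duration_s = 10)
  expect_false(ro$pass)
  expect_equal(ro$occlusion_runs, 1)
  expect_true("occlusion" %in% ro$reasons)

  # QC dropped fraction agrees with the reader's gap bookkeeping
  expect_equal(r6$dropped_fraction, dropped_fraction(s6))
})

test_that("linear detrend removes lines, is idempotent and keeps oscillation", {
  t <- (0:299) / 30
  lin <- distance_waveform(t, 0.2 + 0.01 * t, sample_rate_hz = 30)
  out <- detrend_linear(lin)
  expect_equal(out$d, rep(0, 300), tolerance = 1e-12)
  expect_equal(out$provenance, "detrend")

  # direct least-squares oracle: detrending equals the lm residuals; on an
  # integer number of sine cycles the fitted trend is near-null (exact
  # orthogonality holds only in continuous time, so the discrete-grid
  # slope is small but not zero)
  w <- make_sine_wave(f = 2, A = 0.1, offset = 0.3, fps = 50, duration = 10)
  det <- detrend_linear(w)
  ols <- lm(w$d ~ w$t)
  expect_equal(det$d, unname(residuals(ols)), tolerance = 1e-12)
  expect_lt(abs(coef(ols)[2]), 0.015 * 0.1)  # slope small next to amplitude
  expect_equal(det$d, w$d - mean(w$d), tolerance = 0.1)

  # idempotence and re-fit slope ~ 0
  det2 <- detrend_linear(det)
  expect_equal(det2$d, det$d, tolerance = 1e-12)
  expect_lt(abs(coef(lm(det$d ~ det$t))[2]), 1e-10)

  expect_error(detrend_linear(distance_waveform(0:1, c(1, 2))),
               class = "taplab_invalid_argument")
})

test_that("Savitzky-Golay window rule and polynomial reproduction hold", {
  expect_equal(taplab:::savgol_window(30, 2), 5)    # (30/2)/3 = 5
  expect_equal(taplab:::savgol_window(50, 2), 7)    # floor(25/3) = 8 -> odd 7
  expect_equal(taplab:::savgol_window(30, 4), 5)    # floored at 5

  # an order-2 filter reproduces quadratics exactly, endpoints included
  t <- (0:199) / 30
  q <- distance_waveform(t, 1 + 0.2 * t - 0.05 * t^2, sample_rate_hz = 30)
  sm <- smooth_savgol(q, expected_freq = 2)
  expect_equal(sm$d, q$d, tolerance = 1e-9)

  # white noise is attenuated
  set.seed(11)
  wn <- distance_waveform(t, rnorm(200), sample_rate_hz = 30)
  expect_lt(var(smooth_savgol(wn)$d), var(wn$d))

  short <- distance_waveform((0:3) / 30, rep(1, 4), sample_rate_hz = 30)
  expect_error(smooth_savgol(short), class = "taplab_invalid_argument")
})

test_that("uniform resampling preserves duration, linearity and identity", {
  # already at 50 Hz: identical samples, provenance still appended
  w <- make_sine_wave(fps = 50, duration = 5)
  r <- resample_uniform(w, 50)
  expect_equal(r$d, w$d)
  expect_equal(length(r$provenance), length(w$provenance) + 1L)

  # 30 Hz ramp d = t resamples exactly onto d = t at 50 Hz
  t30 <- (0:449) / 30
  ramp <- distance_waveform(t30, t30, sample_rate_hz = 30)
  r50 <- resample_uniform(ramp, 50)
  expect_equal(r50$d, r50$t, tolerance = 1e-12)
  # 15 s at 30 fps -> 750 samples at 50 Hz
  expect_equal(length(r50$d), 750L)
  expect_equal(r50$sample_rate_hz, 50)

  expect_error(resample_uniform(distance_waveform(0, 1, 30)),
               class = "taplab_invalid_argument")
})

test_that("zero-phase Butterworth has unit DC gain and the expected rolloff", {
  t <- (0:749) / 50
  const <- distance_waveform(t, rep(0.37, 750), sample_rate_hz = 50)
  expect_equal(lowpass_butterworth(const)$d, const$d, tolerance = 1e-9)

  # amplitude oracle via the dominant FFT bin
  amp_at <- function(w, f) {
    sp <- Mod(fft(w$d - mean(w$d))) / (length(w$d) / 2)
    bins <- (seq_along(sp) - 1) * w$sample_rate_hz / length(w$d)
    sp[which.min(abs(bins - f))]
  }
  pass <- distance_waveform(t, sin(2 * pi * 2 * t), sample_rate_hz = 50)
  filt <- lowpass_butterworth(pass)
  expect_gt(amp_at(filt, 2) / amp_at(pass, 2), 0.99)
  # dominant bin unchanged
  sp <- Mod(fft(filt$d - mean(filt$d)))
  half <- 2:(length(sp) / 2)
  expect_equal(which.max(sp[half]), which.max(Mod(fft(pass$d - mean(pass$d)))[half]))

  stopb <- distance_waveform(t, sin(2 * pi * 20 * t), sample_rate_hz = 50)
  expect_lt(amp_at(lowpass_butterworth(stopb), 20) / amp_at(stopb, 20), 0.05)

  expect_error(lowpass_butterworth(pass, cutoff_hz = 25),
               class = "taplab_invalid_argument")
})

test_that("the conditioning pipeline is linear and logs every step in order", {
  t <- (0:449) / 30
  set.seed(3)
  x <- distance_waveform(t, 0.2 + 0.1 * sin(2 * pi * 2 * t) + 0.002 * t,
                         sample_rate_hz = 30)
  y <- distance_waveform(t, 0.1 + 0.05 * cos(2 * pi * 1.5 * t),
                         sample_rate_hz = 30)
  a <- 2; b <- -0.7
  comb <- distance_waveform(t, a * x$d + b * y$d, sample_rate_hz = 30)
  px <- condition_waveform(x); py <- condition_waveform(y)
  pc <- condition_waveform(comb)
  expect_equal(pc$d, a * px$d + b * py$d, tolerance = 1e-9)
  expect_match(px$provenance[1], "detrend")
  expect_match(px$provenance[2], "savgol")
  expect_match(px$provenance[3], "resample")
  expect_match(px$provenance[4], "butterworth")
})
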