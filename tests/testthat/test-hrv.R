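test_that("R peaks of a clean 60 bpm train are found at 1.000 s spacing", {
  e <- synth_ecg_recording(mean_hr_bpm = 60, duration_min = 5, fs_hz = 250,
                           seed = 61)
  r <- detect_r_peaks(e$recording$data[, 1], 250)
  expect_equal(length(r), length(e$r_times_s))
  expect_lte(max(abs(r - e$r_times_s)), 1 / 250 + 1e-12)
  expect_lte(max(abs(diff(r) - 1)), 1 / 250 + 1e-12)
})

test_that("R detection matches generator truth under RR modulation and noise", {
  e <- synth_ecg_recording(mean_hr_bpm = 72,
                           rr_modulations = list(c(0.1, 40), c(0.25, 20)),
                           duration_min = 6, fs_hz = 250, noise_uv = 30,
                           seed = 62)
  r <- detect_r_peaks(e$recording$data[, 1], 250)
  nearest <- vapply(r, function(x) min(abs(e$r_times_s - x)), numeric(1))
  expect_lte(stats::median(nearest), 1 / 250 + 1e-12)
  expect_gte(length(r), 0.98 * length(e$r_times_s))
})

test_that("degenerate ECG inputs raise errors rather than empty successes", {
  expect_error(detect_r_peaks(rep(0, 250 * 30), 250),
               class = "eggwave_validation_error")
  expect_error(detect_r_peaks(rnorm(1000), 50),
               class = "eggwave_validation_error")
})

test_that("RR resampling reproduces constants and linear trends exactly", {
  r_const <- seq(0, 40, by = 0.8)
  out <- build_and_resample_rr(r_const)
  expect_equal(out$rr_ms, rep(800, length(out$t_s)), tolerance = 1e-9)
  expect_equal(diff(out$t_s)[1], 0.25)

  # linearly drifting RR: cubic splines reproduce polynomials of degree 1
  rr_lin <- 800 + 2 * (0:49)
  r_lin <- cumsum(c(0, rr_lin)) / 1000
  out_lin <- build_and_resample_rr(r_lin)
  oracle <- stats::approx(r_lin[-1], rr_lin, xout = out_lin$t_s, rule = 2)$y
  inside <- out_lin$t_s >= r_lin[2] & out_lin$t_s <= max(r_lin)
  expect_equal(out_lin$rr_ms[inside], oracle[inside], tolerance = 1e-6)

  expect_error(build_and_resample_rr(c(0, 1, 0.5, 2)),
               class = "eggwave_validation_error")
  expect_error(build_and_resample_rr(c(0, 1)), class = "eggwave_validation_error")
})

test_that("a sinusoidal RR modulation survives resampling at its frequency", {
  f_mod <- 0.1
  e <- synth_ecg_recording(mean_hr_bpm = 60,
                           rr_modulations = list(c(f_mod, 50)),
                           duration_min = 10, fs_hz = 250, seed = 63)
  out <- build_and_resample_rr(e$r_times_s)
  n <- length(out$rr_ms)
  x <- out$rr_ms - mean(out$rr_ms)
  spec <- (Mod(stats::fft(x * spectral_window(n, "hann")))^2)[1:(n %/% 2)]
  f <- (0:(n %/% 2 - 1)) * 4 / n
  expect_lt(abs(f[which.max(spec)] - f_mod), 4 / n + 1e-12)
})

test_that("time-domain indices equal the literal-formula oracle", {
  expect_equal(hrv_time_domain(rep(1000, 10))$mean_hr_bpm, 60)
  expect_equal(hrv_time_domain(rep(1000, 10))$rmssd_ms, 0)
  expect_equal(hrv_time_domain(rep(1000, 10))$pnn50_pct, 0)

  h <- hrv_time_domain(c(800, 860, 800))
  expect_equal(h$nn50_count, 2L)
  expect_equal(h$rmssd_ms, 60)

  set.seed(64)
  for (i in 1:100) {
    rr <- runif(sample(5:60, 1), 500, 1400)
    got <- hrv_time_domain(rr)
    ora <- hrv_time_oracle(rr)
    for (k in names(ora))
      expect_equal(got[[k]], ora[[k]], tolerance = 1e-12, label = k)
  }
})

test_that("frequency-domain powers land in the modulated band and sum to 100", {
  mk <- function(f_mod) {
    t <- seq(0, 1024 - 0.25, by = 0.25)
    800 + 40 * sin(2 * pi * f_mod * t)
  }
  lf <- hrv_freq_domain(mk(0.1))
  expect_gt(lf$summary$lf_pct, 90)
  hf <- hrv_freq_domain(mk(0.25))
  expect_gt(hf$summary$hf_pct, 90)
  expect_gt(lf$summary$lf_hf_ratio, 1)
  expect_lt(hf$summary$lf_hf_ratio, 1)
  for (w in list(lf, hf)) {
    expect_equal(w$windows$vlf_pct + w$windows$lf_pct + w$windows$hf_pct,
                 rep(100, nrow(w$windows)), tolerance = 1e-6)
    expect_true(all(w$windows$vlf_ms2 >= 0 & w$windows$lf_ms2 >= 0 &
                    w$windows$hf_ms2 >= 0))
  }
  expect_error(hrv_freq_domain(rep(800, 100)), class = "eggwave_validation_error")
})

test_that("the end-to-end HRV pipeline recovers a known LF modulation", {
  e <- synth_ecg_recording(mean_hr_bpm = 60,
                           rr_modulations = list(c(0.1, 50)),
                           duration_min = 10, fs_hz = 250, seed = 65)
  h <- run_hrv(e$recording)
  expect_equal(h$time$mean_rr_ms, 1000, tolerance = 5)
  expect_gt(h$freq$summary$lf_pct, 80)
  expect_equal(h$freq$summary$vlf_pct + h$freq$summary$lf_pct +
               h$freq$summary$hf_pct, 100, tolerance = 1e-6)
})
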