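# Independent oracles and small fixture builders shared across the suite.

# Brute-force DFT periodogram: literal double sum, same scaling contract as
# psd_periodogram (per-cpm density, one-sided doubling).
brute_dft_psd <- function(x, fs, win, lspv) {
  n <- length(x)
  w <- spectral_window(n, win)
  xw <- (x - mean(x)) * w
  nfft <- 2L * lspv
  psd <- vapply(0:(lspv - 1L), function(k)
    Mod(sum(xw * exp(-2i * pi * k * (0:(n - 1L)) / nfft)))^2 / (fs * sum(w^2)),
    numeric(1))
  psd[-1L] <- 2 * psd[-1L]
  psd / 60
}

# Exhaustive AIC minimization: refit each candidate order separately and
# apply the AIC formula literally.
ar_aic_argmin <- function(x, max_order = 30) {
  n <- length(x)
  aics <- vapply(seq_len(max_order), function(k) {
    f <- stats::ar.burg(x, aic = FALSE, order.max = k, demean = TRUE)
    n * log(f$var.pred) + 2 * k
  }, numeric(1))
  which.min(aics)
}

# Literal-formula HRV time-domain oracle (explicit loops).
hrv_time_oracle <- function(rr) {
  n <- length(rr)
  d <- numeric(n - 1)
  for (i in seq_len(n - 1)) d[i] <- rr[i + 1] - rr[i]
  hr <- 60000 / rr
  nn50 <- 0
  for (v in d) if (abs(v) > 50) nn50 <- nn50 + 1
  list(mean_rr_ms = sum(rr) / n,
       std_rr_ms = sqrt(sum((rr - sum(rr) / n)^2) / (n - 1)),
       mean_hr_bpm = sum(hr) / n,
       std_hr_bpm = sqrt(sum((hr - sum(hr) / n)^2) / (n - 1)),
       rmssd_ms = sqrt(sum(d^2) / (n - 1)),
       nn50_count = nn50,
       pnn50_pct = nn50 / n * 100)
}

# Constructed two-peak spectrum: a dominant zero-frequency lobe and a
# secondary peak at `peak_cpm`, `gap_db` below it.
two_peak_spectrum <- function(gap_db, peak_cpm = 3, dc_amp = 1) {
  f <- seq(0, 12, by = 0.05)
  dc <- dc_amp * exp(-(f / 0.12)^2)
  side <- dc_amp * 10^(-gap_db / 10) * exp(-((f - peak_cpm) / 0.25)^2)
  eggwave:::egg_spectrum(f, dc + side + 1e-9, method = "constructed")
}

# Quick 4 Hz clean slow-wave recording (no noise, no need to downsample).
clean_rec_4hz <- function(duration_min = 30, freq_cpm = 3, n_channels = 4,
                          meal_start_s = 0, meal_end_s = 0, seed = 1) {
  synth_egg_recording(freq_cpm = freq_cpm, snr_db = Inf,
                      duration_min = duration_min, fs_hz = 4,
                      n_channels = n_channels, seed = seed,
                      meal_start_s = meal_start_s, meal_end_s = meal_end_s)
}
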