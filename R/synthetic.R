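# Synthetic validation signals: sine-plus-noise slow-wave records with
# defined SNR and 12-bit quantization, injectable motion artifacts, and
# ECG-like trains with known RR modulation for exercising the HRV path.
# The generator defaults reproduce the validation conditions: 90-minute,
# 200 Hz, 12-bit, 4-channel records with slow-wave frequencies in
# 0.5-9 cpm, amplitudes 50-400 uV and SNR in {0, 3, 6, 10} dB.

#' Generate a synthetic multi-channel EGG recording
#'
#' Each EGG channel is `A * sin(2*pi*(freq_cpm/60)*t + phase) + noise`,
#' with white Gaussian noise scaled so that
#' `10*log10(P_signal/P_noise) = snr_db` (noise is drawn independently per
#' channel). The signal is quantized to `adc_bits` through the
#' counts-per-mV scale; by default the scale is chosen so the realized
#' span uses at most 90% of the ADC range, so quantization never clips.
#'
#' @param freq_cpm Slow-wave frequency in cpm (0.5-9), default 3.
#' @param amplitude_uv Sine amplitude in microvolts (nominal 50-400),
#'   default 150.
#' @param snr_db Signal-to-noise ratio in dB; `Inf` (default) disables
#'   noise.
#' @param duration_min Length in minutes, default 90.
#' @param fs_hz Sampling frequency, default 200.
#' @param adc_bits Quantizer resolution, default 12.
#' @param n_channels Number of EGG channels, default 4.
#' @param phases_rad Per-channel phases (recycled); default 0 for all
#'   (perfectly coupled channels).
#' @param seed Random seed (mandatory for reproducibility), default 1.
#' @param noise `"white"` (default) or `"pink"` (1/f, for robustness
#'   experiments).
#' @param meal_start_s,meal_end_s Meal times written to the header,
#'   default 0/0 (no meal).
#' @param counts_per_mv ADC scale; `NULL` (default) picks it from the
#'   realized span. A user-supplied scale that overflows the ADC raises an
#'   error stating the required scale.
#' @param ecg_component Optional `list(freq_hz=, amplitude_uv=)` adding an
#'   ECG-like sinusoidal contaminant to every channel.
#' @return An [egg_recording()] (quantized amplitudes, mV) with attribute
#'   `"truth"`: the generation parameters and the realized per-channel
#'   signal and noise powers.
#' @export
synth_egg_recording <- function(freq_cpm = 3, amplitude_uv = 150, snr_db = Inf,
                                duration_min = 90, fs_hz = 200, adc_bits = 12,
                                n_channels = 4, phases_rad = 0, seed = 1,
                                noise = c("white", "pink"),
                                meal_start_s = 0, meal_end_s = 0,
                                counts_per_mv = NULL, ecg_component = NULL) {
  noise <- match.arg(noise)
  if (freq_cpm < 0.5 || freq_cpm > 9)
    stop_invalid("slow-wave frequency must be 0.5-9 cpm (got %g)", freq_cpm)
  set.seed(seed)
  n <- as.integer(round(duration_min * 60 * fs_hz))
  t <- (seq_len(n) - 1) / fs_hz
  a_mv <- amplitude_uv / 1000
  phases <- rep_len(phases_rad, n_channels)
  sig_power <- a_mv^2 / 2
  noise_sd <- if (is.finite(snr_db)) sqrt(sig_power / db_power(snr_db)) else 0
  data <- matrix(0, n, n_channels)
  noise_power <- numeric(n_channels)
  for (ch in seq_len(n_channels)) {
    s <- a_mv * sin(2 * pi * (freq_cpm / 60) * t + phases[ch])
    e <- if (noise_sd > 0) {
      z <- stats::rnorm(n)
      if (noise == "pink") z <- pink_shape(z)
      z * (noise_sd / stats::sd(z))
    } else rep(0, n)
    if (!is.null(ecg_component))
      s <- s + (ecg_component$amplitude_uv / 1000) *
        sin(2 * pi * ecg_component$freq_hz * t)
    data[, ch] <- s + e
    noise_power[ch] <- mean(e^2)
  }
  lim <- 2^(adc_bits - 1) - 1
  if (is.null(counts_per_mv)) {
    span <- max(abs(data))
    counts_per_mv <- floor(0.9 * lim / span)
    if (counts_per_mv < 1)
      stop_invalid("signal span %g mV exceeds the %d-bit ADC at any scale >= 1",
                   span, adc_bits)
  } else {
    if (max(abs(data)) * counts_per_mv > lim)
      stop_invalid("quantizer overflow: scale must be <= %d counts/mV",
                   floor(lim / max(abs(data))))
  }
  counts <- round(data * counts_per_mv)
  meta <- list(patient_label = "synthetic slow-wave record",
               meal_type = "none",
               meal_start_s = meal_start_s, meal_end_s = meal_end_s,
               fs_hz = fs_hz, adc_bits = as.integer(adc_bits),
               counts_per_mv = counts_per_mv)
  rec <- egg_recording(counts / counts_per_mv, fs_hz,
                       paste0("A", seq_len(n_channels)), meta)
  attr(rec, "truth") <- list(freq_cpm = freq_cpm, amplitude_uv = amplitude_uv,
                             snr_db = snr_db, signal_power_mv2 = sig_power,
                             noise_power_mv2 = noise_power, seed = seed)
  rec
}

# internal: shape white noise to approximately 1/f power (pink)
pink_shape <- function(z) {
  n <- length(z)
  Z <- stats::fft(z)
  k <- c(1, seq_len(n - 1))
  k <- pmin(k, n - k + 1)
  Re(stats::fft(Z / sqrt(k), inverse = TRUE)) / n
}

#' Inject motion-like artifacts into a recording
#'
#' Multiplies the samples of each named interval by a gain, emulating the
#' large-amplitude excursions of movement artifacts. Overlapping intervals
#' are merged with a warning.
#'
#' @param rec An [egg_recording()].
#' @param artifact_spec List of `list(t_min=, duration_s=, gain=)` entries
#'   (interval start in minutes).
#' @param channels Channel labels to corrupt; default all EGG channels.
#' @return The corrupted [egg_recording()].
#' @export
inject_artifacts <- function(rec, artifact_spec,
                             channels = grep("^A[1-4]$", rec$channels,
                                             value = TRUE)) {
  n <- nrow(rec$data)
  dur <- rec_duration_s(rec)
  iv <- lapply(artifact_spec, function(a) {
    t0 <- a$t_min * 60
    t1 <- t0 + a$duration_s
    if (t0 < 0 || t1 > dur)
      stop_invalid("artifact interval (%g min + %g s) outside the recording",
                   a$t_min, a$duration_s)
    c(t0, t1, a$gain)
  })
  iv <- iv[order(vapply(iv, `[`, numeric(1), 1L))]
  if (length(iv) > 1L) {
    merged <- list(iv[[1]])
    for (k in 2L:length(iv)) {
      last <- merged[[length(merged)]]
      if (iv[[k]][1] < last[2]) {
        warning("overlapping artifact intervals merged")
        merged[[length(merged)]] <- c(last[1], max(last[2], iv[[k]][2]),
                                      max(last[3], iv[[k]][3]))
      } else merged[[length(merged) + 1L]] <- iv[[k]]
    }
    iv <- merged
  }
  out <- rec$data
  for (seg in iv) {
    i0 <- max(1L, as.integer(floor(seg[1] * rec$fs_hz)) + 1L)
    i1 <- min(n, as.integer(ceiling(seg[2] * rec$fs_hz)))
    for (ch in channels) out[i0:i1, ch] <- out[i0:i1, ch] * seg[3]
  }
  rec2 <- egg_recording(out, rec$fs_hz, rec$channels, rec$meta)
  attr(rec2, "truth") <- attr(rec, "truth")
  rec2
}

#' Generate an ECG-like recording with known RR modulation
#'
#' Repeats a raised-cosine QRS template (with a small T wave) at intervals
#' `rr(t) = 60000/mean_hr_bpm + sum(depth * sin(2*pi*f*t))` ms and returns
#' the ground-truth R times alongside the signal, enabling end-to-end
#' verification of the HRV path.
#'
#' @param mean_hr_bpm Mean heart rate, default 60.
#' @param rr_modulations List of `c(freq_hz, depth_ms)` sinusoidal RR
#'   modulations (may be empty).
#' @param duration_min Length in minutes, default 10.
#' @param fs_hz Sampling frequency, default 250.
#' @param noise_uv White-noise SD added to the trace in microvolts,
#'   default 0.
#' @param seed Random seed, default 1.
#' @return List: `recording` (single-channel [egg_recording()]),
#'   `r_times_s` (ground-truth R-peak times, on the sample grid).
#' @export
synth_ecg_recording <- function(mean_hr_bpm = 60, rr_modulations = list(),
                                duration_min = 10, fs_hz = 250, noise_uv = 0,
                                seed = 1) {
  set.seed(seed)
  n <- as.integer(round(duration_min * 60 * fs_hz))
  dur <- n / fs_hz
  rr_ms <- function(t) {
    v <- 60000 / mean_hr_bpm
    for (m in rr_modulations) v <- v + m[2] * sin(2 * pi * m[1] * t)
    v
  }
  # QRS: 80 ms raised cosine, peak on a sample; small T wave 300 ms later
  qw <- as.integer(round(0.04 * fs_hz))
  qrs <- cos(pi * (-qw:qw) / (2 * qw))^2
  tw <- as.integer(round(0.08 * fs_hz))
  twave <- 0.15 * cos(pi * (-tw:tw) / (2 * tw))^2
  x <- rep(0, n)
  r_times <- numeric(0)
  t_k <- 0.5
  while (t_k < dur - 0.5) {
    ci <- as.integer(round(t_k * fs_hz)) + 1L
    idx <- (ci - qw):(ci + qw)
    ok <- idx >= 1L & idx <= n
    x[idx[ok]] <- x[idx[ok]] + qrs[ok]
    ti <- ci + as.integer(round(0.3 * fs_hz))
    idx <- (ti - tw):(ti + tw)
    ok <- idx >= 1L & idx <= n
    x[idx[ok]] <- x[idx[ok]] + twave[ok]
    r_times <- c(r_times, (ci - 1L) / fs_hz)
    rr <- rr_ms(t_k) / 1000
    if (rr <= 2 * qw / fs_hz)
      stop_invalid("RR interval (%g s) shorter than the QRS template", rr)
    t_k <- t_k + rr
  }
  if (noise_uv > 0) x <- x + stats::rnorm(n, sd = noise_uv / 1000)
  meta <- list(patient_label = "synthetic ECG-like record", meal_type = "",
               meal_start_s = 0, meal_end_s = 0, fs_hz = fs_hz,
               adc_bits = NA_integer_, counts_per_mv = 1000)
  list(recording = egg_recording(matrix(x, ncol = 1), fs_hz, "A1", meta),
       r_times_s = r_times)
}
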