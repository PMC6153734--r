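# Optional heart-rate-variability sub-pipeline for recordings sampled fast
# enough (>= 100 Hz, nominally 250 Hz) to contain the ECG: Pan-Tompkins
# R-peak detection, RR tachogram construction with 4 Hz cubic-spline
# resampling, and the standard time- and frequency-domain indices.

#' Detect R peaks with the Pan-Tompkins algorithm
#'
#' Stages: zero-phase 5-15 Hz band-pass, five-point derivative, squaring,
#' 150 ms moving-window integration, adaptive dual-threshold peak picking
#' with a 200 ms refractory period and RR-gap search-back at half
#' threshold. Peak times are refined to the local maximum of the
#' band-passed signal (zero-phase, so aligned with the raw QRS).
#'
#' @param x Numeric vector: ECG-like channel.
#' @param fs Sampling frequency in Hz; must be >= 100 (a warning is issued
#'   below the nominal 250 Hz).
#' @return Ascending vector of R-peak times in seconds (>= 2 peaks, else an
#'   error).
#' @export
detect_r_peaks <- function(x, fs) {
  if (fs < 100) stop_invalid("R-peak detection needs fs >= 100 Hz (got %g)", fs)
  if (fs < 250) warning("fs below the nominal 250 Hz; R timing may lose precision")
  if (stats::sd(x) == 0) stop_invalid("flat signal: no QRS complexes present")
  bp <- signal::filtfilt(signal::butter(3, c(5, 15) / (fs / 2), type = "pass"), x)
  # five-point derivative, causal (2-sample delay)
  der <- stats::filter(bp, c(1, 2, 0, -2, -1) * fs / 8, method = "convolution",
                       sides = 1)
  der[is.na(der)] <- 0
  sq <- as.numeric(der)^2
  nwin <- max(2L, as.integer(round(0.150 * fs)))
  mwi <- stats::filter(sq, rep(1 / nwin, nwin), method = "convolution", sides = 1)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)
  delay <- 2L + as.integer((nwin - 1L) %/% 2L)

  refractory <- as.integer(round(0.200 * fs))
  pk <- local_maxima(mwi)
  # enforce refractory spacing among candidates, keeping the larger peak
  if (length(pk) > 1L) {
    keep <- logical(length(pk))
    last <- 1L; keep[1L] <- TRUE
    for (i in 2L:length(pk)) {
      if (pk[i] - pk[last] >= refractory) { keep[i] <- TRUE; last <- i }
      else if (mwi[pk[i]] > mwi[pk[last]]) { keep[last] <- FALSE; keep[i] <- TRUE; last <- i }
    }
    pk <- pk[keep]
  }
  if (length(pk) < 2L) stop_invalid("fewer than 2 candidate QRS peaks found")

  init <- seq_len(min(length(mwi), as.integer(2 * fs)))
  spki <- 0.25 * max(mwi[init])
  npki <- 0.5 * mean(mwi[init])
  thr <- function() npki + 0.25 * (spki - npki)
  qrs <- integer(0)
  rr_hist <- numeric(0)
  for (i in seq_along(pk)) {
    p <- pk[i]; v <- mwi[p]
    if (v > thr()) {
      qrs <- c(qrs, p)
      spki <- 0.125 * v + 0.875 * spki
      if (length(qrs) >= 2L)
        rr_hist <- utils::tail(c(rr_hist, diff(utils::tail(qrs, 2L))), 8L)
    } else {
      npki <- 0.125 * v + 0.875 * npki
      # search-back: accept a sub-threshold peak at half threshold when the
      # expected beat is overdue
      if (length(qrs) >= 2L && length(rr_hist) > 0L &&
          (p - qrs[length(qrs)]) > 1.66 * mean(rr_hist) && v > 0.5 * thr()) {
        qrs <- c(qrs, p)
        spki <- 0.25 * v + 0.75 * spki
        rr_hist <- utils::tail(c(rr_hist, diff(utils::tail(qrs, 2L))), 8L)
      }
    }
  }
  if (length(qrs) < 2L) stop_invalid("fewer than 2 QRS complexes detected")
  # refine to the band-passed local maximum near the delay-compensated index
  half <- as.integer(round(0.100 * fs))
  r_idx <- vapply(qrs, function(p) {
    c0 <- max(1L, p - delay - half)
    c1 <- min(length(bp), p - delay + half)
    c0 + which.max(bp[c0:c1]) - 1L
  }, integer(1))
  r_idx <- sort(unique(r_idx))
  r_idx <- r_idx[c(TRUE, diff(r_idx) >= refractory)]
  (r_idx - 1L) / fs
}

#' Build the RR tachogram and resample it to a uniform 4 Hz grid
#'
#' Successive R-peak differences (ms) form an irregularly sampled series
#' (each RR value is placed at the time of its later R peak); a natural
#' cubic spline through these points is evaluated on a uniform `fs_out`
#' grid spanning the first to last R time.
#'
#' @param r_times_s Ascending R-peak times in seconds (>= 4).
#' @param fs_out Output rate in Hz, default 4.
#' @return List `t_s` (grid times), `rr_ms` (resampled series), and the
#'   raw `r_times_s` / `rr_raw_ms`.
#' @export
build_and_resample_rr <- function(r_times_s, fs_out = 4) {
  if (length(r_times_s) < 4L) stop_invalid("need at least 4 R peaks")
  if (any(diff(r_times_s) <= 0)) stop_invalid("R-peak times must be strictly increasing")
  rr <- diff(r_times_s) * 1000
  sf <- stats::splinefun(r_times_s[-1L], rr, method = "natural")
  t_grid <- seq(r_times_s[1L], r_times_s[length(r_times_s)], by = 1 / fs_out)
  list(t_s = t_grid, rr_ms = sf(t_grid), r_times_s = r_times_s, rr_raw_ms = rr)
}

#' Time-domain HRV indices
#'
#' Mean and SD of the RR intervals and of the instantaneous heart rate
#' (60000/RR), RMSSD (root mean square of successive differences), NN50
#' (successive pairs differing by more than 50 ms) and pNN50 (NN50 over
#' the total number of RR intervals).
#'
#' @param rr_ms Numeric vector of RR intervals in ms (>= 2).
#' @return Named list of `mean_rr_ms`, `std_rr_ms`, `mean_hr_bpm`,
#'   `std_hr_bpm`, `rmssd_ms`, `nn50_count`, `pnn50_pct`.
#' @export
hrv_time_domain <- function(rr_ms) {
  if (length(rr_ms) < 2L) stop_invalid("need at least 2 RR intervals")
  if (any(rr_ms <= 0)) stop_invalid("RR intervals must be positive")
  d <- diff(rr_ms)
  hr <- 60000 / rr_ms
  list(mean_rr_ms = mean(rr_ms), std_rr_ms = sd0(rr_ms),
       mean_hr_bpm = mean(hr), std_hr_bpm = sd0(hr),
       rmssd_ms = sqrt(mean(d^2)),
       nn50_count = sum(abs(d) > 50),
       pnn50_pct = sum(abs(d) > 50) / length(rr_ms) * 100)
}

# internal: linear detrend
detrend_linear <- function(y) {
  t <- seq_along(y)
  stats::lm.fit(cbind(1, t), y)$residuals
}

#' Frequency-domain HRV indices
#'
#' Welch-style analysis of the uniformly resampled RR series: overlapping
#' windows (256 s length, 128 s overlap by default), linear detrend and
#' Hann taper per window, periodogram, and trapezoidal band powers over
#' VLF 0.003-0.04 Hz, LF 0.04-0.15 Hz and HF 0.15-0.40 Hz. Relative powers
#' are referred to total = VLF + LF + HF. Summary values are the means over
#' windows.
#'
#' @param rr_resampled List from [build_and_resample_rr()] (or a numeric
#'   vector of the uniform RR series in ms).
#' @param fs Sampling rate of the series (default 4 Hz).
#' @param window_s Window length in seconds, default 256.
#' @param overlap_s Window overlap in seconds, default 128.
#' @param bands VLF/LF/HF edges in Hz.
#' @return List of class `egg_hrv_freq`: `windows` (data frame, one row per
#'   window) and `summary` (means over windows: absolute powers in ms^2,
#'   relative powers in %, LF/HF ratio).
#' @export
hrv_freq_domain <- function(rr_resampled, fs = 4, window_s = 256,
                            overlap_s = 128,
                            bands = list(vlf = c(0.003, 0.04),
                                         lf = c(0.04, 0.15),
                                         hf = c(0.15, 0.40))) {
  x <- if (is.list(rr_resampled)) rr_resampled$rr_ms else rr_resampled
  nwin <- as.integer(round(window_s * fs))
  step <- as.integer(round((window_s - overlap_s) * fs))
  if (length(x) < nwin)
    stop_invalid("series (%d samples) shorter than one %g s window",
                 length(x), window_s)
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  w <- spectral_window(nwin, "hann")
  rows <- lapply(starts, function(s) {
    seg <- detrend_linear(x[s:(s + nwin - 1L)]) * w
    nfft <- 2L * nwin
    X <- stats::fft(c(seg, rep(0, nfft - nwin)))
    psd <- Mod(X[seq_len(nwin)])^2 / (fs * sum(w^2))
    psd[-1L] <- 2 * psd[-1L]
    f <- (seq_len(nwin) - 1L) * fs / nfft
    pw <- vapply(bands, function(b) integrate_band(f, psd, b[1], b[2]),
                 numeric(1))
    tot <- sum(pw)
    data.frame(t_start_s = (s - 1L) / fs,
               vlf_ms2 = pw[["vlf"]], lf_ms2 = pw[["lf"]], hf_ms2 = pw[["hf"]],
               vlf_pct = pw[["vlf"]] / tot * 100,
               lf_pct = pw[["lf"]] / tot * 100,
               hf_pct = pw[["hf"]] / tot * 100,
               lf_hf_ratio = pw[["lf"]] / pw[["hf"]])
  })
  windows <- do.call(rbind, rows)
  summary <- as.list(colMeans(windows[, -1L, drop = FALSE]))
  structure(list(windows = windows, summary = summary), class = "egg_hrv_freq")
}

#' Run the full HRV sub-pipeline
#'
#' Either detects R peaks on an ECG-bearing channel of a high-rate
#' recording, or starts from a supplied R-peak time series; then computes
#' time-domain indices on the raw RR intervals and frequency-domain indices
#' on the 4 Hz spline-resampled series.
#'
#' @param rec Optional [egg_recording()] sampled at >= 100 Hz.
#' @param channel Channel label to detect on (default first EGG channel).
#' @param r_times_s Optional precomputed R-peak times (bypasses detection).
#' @param window_s,overlap_s Spectral window geometry, defaults 256/128 s.
#' @return List of class `egg_hrv`: `r_times_s`, `rr_ms`, `time` (indices),
#'   `freq` (an `egg_hrv_freq`).
#' @export
run_hrv <- function(rec = NULL, channel = NULL, r_times_s = NULL,
                    window_s = 256, overlap_s = 128) {
  if (is.null(r_times_s)) {
    stopifnot(inherits(rec, "egg_recording"))
    channel <- channel %||% rec$channels[1]
    r_times_s <- detect_r_peaks(rec$data[, channel], rec$fs_hz)
  }
  res <- build_and_resample_rr(r_times_s)
  structure(list(r_times_s = r_times_s, rr_ms = res$rr_raw_ms,
                 time = hrv_time_domain(res$rr_raw_ms),
                 freq = hrv_freq_domain(res, window_s = window_s,
                                        overlap_s = overlap_s)),
            class = "egg_hrv")
}

#' Read a two-column RR text file
#'
#' Column 1: time of the R peak in seconds; column 2: RR interval in ms
#' (ignored beyond validation -- intervals are rebuilt from the times when
#' they disagree by more than 1 ms).
#'
#' @param path Path to a whitespace-separated two-column text file.
#' @return Ascending vector of R-peak times in seconds.
#' @export
read_rr_file <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  d <- utils::read.table(path, header = FALSE)
  if (ncol(d) < 1L) stop_format("empty RR file: %s", path)
  t <- d[[1]]
  if (any(diff(t) <= 0)) stop_format("RR times not strictly increasing in %s", path)
  t
}
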