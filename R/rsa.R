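# Running Spectrum Analysis (RSA): overlapping segmentation, per-segment PSD
# estimation (Burg AR with AIC order selection, or windowed periodograms),
# dominant frequency/power extraction with the 2.5 dB correction rule, and
# gastric rhythm classification.

#' RSA configuration
#'
#' @param lseg_s Segment length in seconds (60-256; default 240).
#' @param sseg_s Overlap between consecutive segments in seconds
#'   (`0 <= sseg_s < lseg_s`; default 120).
#' @param lspv Number of one-sided spectral samples covering `[0, fs/2)`
#'   (default 4096).
#' @param normo_cpm Normogastria band in cpm, default `c(2, 4)`.
#' @param method PSD estimator: `"periodogram_tukey"` (Tukey window,
#'   alpha = 0.25; default), `"periodogram_barthann"`, `"periodogram_hann"`
#'   or `"ar_aic"` (Burg autoregressive spectrum, AIC-selected order + 6).
#' @param df_range_cpm Valid dominant-frequency range, default `c(0.5, 9)`.
#' @param max_ar_order Largest candidate AR order for AIC search (default 30).
#' @return An `rsa_config` list.
#' @export
rsa_config <- function(lseg_s = 240, sseg_s = 120, lspv = 4096,
                       normo_cpm = c(2, 4),
                       method = c("periodogram_tukey", "periodogram_barthann",
                                  "periodogram_hann", "ar_aic"),
                       df_range_cpm = c(0.5, 9), max_ar_order = 30) {
  method <- match.arg(method)
  if (lseg_s < 60 || lseg_s > 256)
    stop_invalid("segment length must be 60-256 s (got %g)", lseg_s)
  if (sseg_s < 0 || sseg_s >= lseg_s)
    stop_invalid("overlap must satisfy 0 <= sseg < lseg")
  if (normo_cpm[1] >= normo_cpm[2]) stop_invalid("normogastria band inverted")
  structure(list(lseg_s = lseg_s, sseg_s = sseg_s, lspv = lspv,
                 normo_cpm = normo_cpm, method = method,
                 df_range_cpm = df_range_cpm, max_ar_order = max_ar_order),
            class = "rsa_config")
}

#' Split a signal into overlapping analysis segments
#'
#' The first segment starts at t = 0; each subsequent segment advances by
#' `lseg_s - sseg_s` seconds (so it shares `sseg_s` seconds with its
#' predecessor). A trailing partial segment is dropped.
#'
#' @param x Numeric vector (one channel).
#' @param fs Sampling frequency in Hz.
#' @param lseg_s Segment length in seconds.
#' @param sseg_s Overlap in seconds.
#' @return List of `list(t_start_s, samples)`.
#' @export
segment_signal <- function(x, fs, lseg_s = 240, sseg_s = 120) {
  seg_n <- as.integer(round(lseg_s * fs))
  step_n <- as.integer(round((lseg_s - sseg_s) * fs))
  if (length(x) < seg_n)
    stop_invalid("signal (%d samples) shorter than one %g s segment",
                 length(x), lseg_s)
  starts <- seq(1L, length(x) - seg_n + 1L, by = step_n)
  lapply(starts, function(s)
    list(t_start_s = (s - 1L) / fs, samples = x[s:(s + seg_n - 1L)]))
}

#' Select the AR model order by the Akaike information criterion
#'
#' Fits Burg autoregressive models of orders `1..max_order` to the (windowed)
#' segment, takes the AIC-minimizing order and adds 6, a constant increase
#' that sharpens spectral detail for short gastric signals. A degenerate
#' (near-constant) segment falls back to order 1 + 6.
#'
#' @param x Numeric vector: the windowed analysis segment.
#' @param max_order Largest candidate order (default 30).
#' @param add Constant added to the AIC-optimal order (default 6).
#' @return Integer model order.
#' @export
select_ar_order <- function(x, max_order = 30, add = 6) {
  if (length(x) <= max_order + 1L)
    stop_invalid("segment too short (%d samples) for order search up to %d",
                 length(x), max_order)
  if (stats::sd(x) < .Machine$double.eps * max(1, abs(mean(x))))
    return(1L + add)
  fit <- stats::ar.burg(x, aic = TRUE, order.max = max_order, demean = TRUE)
  aics <- fit$aic[as.character(seq_len(max_order))]
  as.integer(which.min(aics)) + add
}

# internal: Spectrum container
egg_spectrum <- function(freq_cpm, psd, method, meta = list()) {
  psd <- pmax(psd, 0)
  structure(list(freq_cpm = freq_cpm, psd = psd, method = method, meta = meta),
            class = "egg_spectrum")
}

#' @export
print.egg_spectrum <- function(x, ...) {
  cat(sprintf("<egg_spectrum> %d bins, %.3f-%.2f cpm, method %s\n",
              length(x$freq_cpm), min(x$freq_cpm), max(x$freq_cpm), x$method))
  invisible(x)
}

#' @export
plot.egg_spectrum <- function(x, db = TRUE, xlim = c(0, 12), ...) {
  y <- if (db) power_db(x$psd) else x$psd
  graphics::plot(x$freq_cpm, y, type = "l", xlim = xlim,
                 xlab = "frequency [cpm]",
                 ylab = if (db) "PSD [dB re 1 mV²/cpm]" else "PSD [mV²/cpm]",
                 ...)
  invisible(x)
}

#' Burg autoregressive power spectral density of one segment
#'
#' The segment is tapered with the Tukey (alpha = 0.25) window, the AR order
#' is chosen with [select_ar_order()] (AIC minimum + 6), and the AR spectrum
#' `sigma^2 / (fs * |1 - sum a_j exp(-2 pi i f j / fs)|^2)` is evaluated on
#' `lspv` points over `[0, fs/2)`. Frequencies are reported in cpm and power
#' in mV^2/cpm.
#'
#' @param x Numeric vector: one analysis segment (mV).
#' @param fs Sampling frequency in Hz.
#' @param lspv Number of spectral samples.
#' @param order AR order; `NULL` (default) selects it by AIC.
#' @param window Taper applied before fitting (default Tukey 0.25).
#' @return An `egg_spectrum`.
#' @export
psd_ar <- function(x, fs, lspv = 4096, order = NULL, window = "tukey") {
  w <- spectral_window(length(x), window)
  xw <- (x - mean(x)) * w
  if (is.null(order)) order <- select_ar_order(xw)
  if (order >= length(xw)) stop_invalid("AR order %d >= segment length", order)
  fit <- stats::ar.burg(xw, aic = FALSE, order.max = order, demean = TRUE)
  a <- fit$ar
  if (any(!is.finite(a)))
    stop_invalid("unstable AR fit (order %d) for this segment", order)
  f_hz <- seq(0, fs / 2, length.out = lspv + 1L)[seq_len(lspv)]
  ej <- exp(-2i * pi * outer(f_hz / fs, seq_along(a)))
  denom <- Mod(1 - as.vector(ej %*% a))^2
  psd_hz <- fit$var.pred / (fs * denom)
  # per-cpm density; taper power loss compensated so levels are comparable
  # with the periodogram estimators
  psd_cpm <- psd_hz / 60 / mean(w^2)
  egg_spectrum(f_hz * 60, psd_cpm, method = "ar",
               meta = list(order = order, var_pred = fit$var.pred))
}

#' Windowed, zero-padded periodogram of one segment
#'
#' The demeaned segment is tapered, zero-padded and transformed with an FFT
#' of length `2 * lspv`; the one-sided spectrum on `lspv` points over
#' `[0, fs/2)` is scaled by `1 / (fs * sum(w^2))` (so a unit-variance white
#' input has the same mean level whatever the window) and doubled at
#' non-DC bins. Frequencies in cpm, power in mV^2/cpm.
#'
#' @param x Numeric vector: one analysis segment (mV).
#' @param fs Sampling frequency in Hz.
#' @param window `"tukey"` (alpha = 0.25), `"barthann"`, `"hann"` or `"rect"`.
#' @param lspv Number of one-sided spectral samples (`>=` segment length).
#' @param demean Subtract the segment mean first (default `TRUE`).
#' @return An `egg_spectrum`.
#' @export
psd_periodogram <- function(x, fs, window = c("tukey", "barthann", "hann", "rect"),
                            lspv = 4096, demean = TRUE) {
  window <- match.arg(window)
  n <- length(x)
  if (lspv < n) stop_invalid("lspv (%d) must be >= segment length (%d)", lspv, n)
  w <- spectral_window(n, window)
  xw <- (if (demean) x - mean(x) else x) * w
  nfft <- 2L * as.integer(lspv)
  X <- stats::fft(c(xw, rep(0, nfft - n)))
  psd_hz <- Mod(X[seq_len(lspv)])^2 / (fs * sum(w^2))
  psd_hz[-1L] <- 2 * psd_hz[-1L]      # one-sided: fold negative frequencies
  f_hz <- (seq_len(lspv) - 1L) * fs / nfft
  egg_spectrum(f_hz * 60, psd_hz / 60, method = paste0("periodogram_", window),
               meta = list(window = window, n = n))
}

# internal: indices of strict local maxima of a vector
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

#' Locate the dominant spectral peak with the 2.5 dB correction rule
#'
#' The dominant frequency (DF) is the frequency of the highest PSD value.
#' If that maximum lies inside `df_range_cpm` it is accepted directly. If
#' the global maximum sits in the zero-frequency region (below the lower
#' range edge), the next spectral maximum is examined: when it lies in
#' range and the dB gap between the first and second maxima is less than
#' `gap_db` (2.5 dB), the DF is corrected to the second maximum; otherwise
#' the segment is classified arrhythmic and carries no DF/DP. The dominant
#' power (DP) is `10*log10` of the PSD at the DF.
#'
#' @param spec An `egg_spectrum`.
#' @param df_range_cpm Valid DF range in cpm, default `c(0.5, 9)`.
#' @param gap_db Correction-rule gap, default 2.5 dB.
#' @param dc_guard_cpm Local maxima at or below this frequency are treated
#'   as part of the DC lobe and never promoted (default 0.25 cpm).
#' @return List `df_cpm`, `dp_db` (both `NA` when arrhythmic), `corrected`,
#'   `arrhythmia`.
#' @export
find_dominant <- function(spec, df_range_cpm = c(0.5, 9), gap_db = 2.5,
                          dc_guard_cpm = 0.25) {
  f <- spec$freq_cpm
  p <- spec$psd
  if (max(f) < df_range_cpm[2])
    stop_invalid("spectrum does not cover the DF range up to %g cpm",
                 df_range_cpm[2])
  if (all(p <= 0))
    return(list(df_cpm = NA_real_, dp_db = NA_real_,
                corrected = FALSE, arrhythmia = TRUE))
  imax <- which.max(p)            # which.max: ties -> lowest frequency
  fmax <- f[imax]
  if (fmax >= df_range_cpm[1] && fmax <= df_range_cpm[2]) {
    return(list(df_cpm = fmax, dp_db = power_db(p[imax]),
                corrected = FALSE, arrhythmia = FALSE))
  }
  if (fmax < df_range_cpm[1]) {
    # DC-region maximum: look for the next maximum outside the DC lobe
    cand <- local_maxima(p)
    cand <- cand[f[cand] > dc_guard_cpm & cand != imax &
                 f[cand] >= df_range_cpm[1] & f[cand] <= df_range_cpm[2]]
    if (length(cand) > 0L) {
      i2 <- cand[which.max(p[cand])]
      gap <- power_db(p[imax]) - power_db(p[i2])
      if (gap < gap_db) {
        return(list(df_cpm = f[i2], dp_db = power_db(p[i2]),
                    corrected = TRUE, arrhythmia = FALSE))
      }
    }
  }
  list(df_cpm = NA_real_, dp_db = NA_real_, corrected = FALSE, arrhythmia = TRUE)
}

#' Classify the gastric rhythm of a segment from its dominant frequency
#'
#' @param df_cpm Dominant frequency in cpm, or `NA` for an arrhythmic
#'   segment.
#' @param normo_cpm Normogastria band `c(low, high)` in cpm (inclusive),
#'   default `c(2, 4)`.
#' @param df_range_cpm Valid DF range, default `c(0.5, 9)`.
#' @return One of `"bradygastria"`, `"normogastria"`, `"tachygastria"`,
#'   `"arrhythmia"`.
#' @export
classify_rhythm <- function(df_cpm, normo_cpm = c(2, 4), df_range_cpm = c(0.5, 9)) {
  if (is.na(df_cpm)) return("arrhythmia")
  if (df_cpm < df_range_cpm[1] || df_cpm > df_range_cpm[2]) return("arrhythmia")
  if (df_cpm < normo_cpm[1]) return("bradygastria")
  if (df_cpm <= normo_cpm[2]) return("normogastria")
  "tachygastria"
}

# internal: PSD of one segment under an rsa_config
segment_psd <- function(samples, fs, cfg) {
  switch(cfg$method,
    ar_aic = psd_ar(samples, fs, lspv = cfg$lspv),
    periodogram_tukey = psd_periodogram(samples, fs, "tukey", cfg$lspv),
    periodogram_barthann = psd_periodogram(samples, fs, "barthann", cfg$lspv),
    periodogram_hann = psd_periodogram(samples, fs, "hann", cfg$lspv))
}

#' Run the Running Spectrum Analysis over all EGG channels
#'
#' Segments every EGG channel (shared grid), estimates a PSD per segment,
#' extracts DF/DP with the 2.5 dB correction rule and classifies the
#' rhythm. Segments overlapping an artifact tile are excluded in every
#' channel and carry no DF/DP.
#'
#' @param rec An [egg_recording()] at 4 Hz (already downsampled and
#'   band-passed).
#' @param mask Optional combined [artifact_mask()].
#' @param cfg An [rsa_config()].
#' @param keep_spectra Keep every per-segment spectrum in the result
#'   (memory-hungry; default `FALSE`).
#' @return A list of class `egg_rsa`: `segments` (data frame with one row
#'   per segment per channel: `channel`, `segment`, `t_start_s`, `excluded`,
#'   `df_cpm`, `dp_db`, `rhythm`, `corrected`), `config`, and `spectra`
#'   (when kept: `spectra[[channel]][[segment]]`).
#' @export
run_rsa <- function(rec, mask = NULL, cfg = rsa_config(), keep_spectra = FALSE) {
  stopifnot(inherits(rec, "egg_recording"))
  ch_idx <- which(grepl("^A[1-4]$", rec$channels))
  rows <- list()
  spectra <- if (keep_spectra) list() else NULL
  for (ci in ch_idx) {
    ch <- rec$channels[ci]
    segs <- segment_signal(rec$data[, ci], rec$fs_hz, cfg$lseg_s, cfg$sseg_s)
    ch_spec <- if (keep_spectra) vector("list", length(segs)) else NULL
    for (si in seq_along(segs)) {
      s <- segs[[si]]
      excl <- mask_excludes(mask, s$t_start_s, s$t_start_s + cfg$lseg_s)
      if (excl) {
        rows[[length(rows) + 1L]] <- data.frame(
          channel = ch, segment = si, t_start_s = s$t_start_s, excluded = TRUE,
          df_cpm = NA_real_, dp_db = NA_real_, rhythm = "excluded",
          corrected = FALSE, stringsAsFactors = FALSE)
        next
      }
      spec <- tryCatch(segment_psd(s$samples, rec$fs_hz, cfg),
                       error = function(e)
                         stop_invalid("channel %s segment %d: %s", ch, si,
                                      conditionMessage(e)))
      dom <- find_dominant(spec, cfg$df_range_cpm)
      if (keep_spectra) ch_spec[[si]] <- spec
      rows[[length(rows) + 1L]] <- data.frame(
        channel = ch, segment = si, t_start_s = s$t_start_s, excluded = FALSE,
        df_cpm = dom$df_cpm, dp_db = dom$dp_db,
        rhythm = classify_rhythm(dom$df_cpm, cfg$normo_cpm, cfg$df_range_cpm),
        corrected = dom$corrected, stringsAsFactors = FALSE)
    }
    if (keep_spectra) spectra[[ch]] <- ch_spec
  }
  structure(list(segments = do.call(rbind, rows), config = cfg,
                 spectra = spectra),
            class = "egg_rsa")
}
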