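# Preprocessing: band extraction of the gastric slow wave, anti-alias
# downsampling of high-rate recordings to 4 Hz, and artifact flagging by
# standard-deviation thresholding.

#' Band-pass filter specification
#'
#' @param method One of `"butterworth"` (4th-order design, applied
#'   forward-and-reverse for zero phase), `"zero_phase_inverse_butterworth"`
#'   (band-stop complement: output = input minus the band-stop-filtered
#'   input, both passes zero-phase) or `"ib_dct"` (index-blocked discrete
#'   cosine transform: whole-signal DCT masking).
#' @param low_hz,high_hz Pass-band edges in Hz; `0 <= low_hz < high_hz <= 0.5`.
#'   Defaults bracket the gastric slow-wave band 0.5-9 cpm (0.008-0.15 Hz).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(method = c("butterworth", "zero_phase_inverse_butterworth",
                                   "ib_dct"),
                        low_hz = 0.008, high_hz = 0.15) {
  method <- match.arg(method)
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz <= 0.5))
    stop_invalid("pass band must satisfy 0 <= low < high <= 0.5 Hz (got %g-%g)",
                 low_hz, high_hz)
  structure(list(method = method, low_hz = low_hz, high_hz = high_hz),
            class = "filter_spec")
}

# internal: zero-phase 4th-order Butterworth band-pass of one channel
bandpass_butter <- function(x, fs, low_hz, high_hz) {
  nyq <- fs / 2
  hi <- min(high_hz, nyq * 0.999)
  if (low_hz <= 0) {
    flt <- signal::butter(4, hi / nyq, type = "low")
  } else {
    flt <- signal::butter(4, c(low_hz, hi) / nyq, type = "pass")
  }
  signal::filtfilt(flt, x)
}

# internal: band-stop complement ("inverse") variant
bandstop_complement <- function(x, fs, low_hz, high_hz) {
  nyq <- fs / 2
  hi <- min(high_hz, nyq * 0.999)
  if (low_hz <= 0) {
    # stop band degenerates to a high-pass above hi
    flt <- signal::butter(4, hi / nyq, type = "high")
  } else {
    flt <- signal::butter(4, c(low_hz, hi) / nyq, type = "stop")
  }
  x - signal::filtfilt(flt, x)
}

# internal: DCT-II coefficient masking via the even-extension FFT identity.
# Masking DCT index k is equivalent to zeroing FFT bins k and 2N-k of the
# even extension c(x, rev(x)); coefficient k maps to f_k = k*fs/(2N).
dct_mask_filter <- function(x, fs, low_hz, high_hz) {
  n <- length(x)
  v <- c(x, rev(x))
  V <- stats::fft(v)
  k <- 0:(2 * n - 1)
  kk <- pmin(k, 2 * n - k)           # mirrored index for the upper half
  f <- kk * fs / (2 * n)
  keep <- f >= low_hz & f <= high_hz
  V[!keep] <- 0
  Re(stats::fft(V, inverse = TRUE))[seq_len(n)] / (2 * n)
}

#' Extract the EGG band from a recording
#'
#' Applies the chosen zero-phase band-pass to every EGG channel (A1-A4);
#' an auxiliary sensor channel is passed through untouched.
#'
#' @param rec An [egg_recording()].
#' @param spec A [filter_spec()]; default is the 0.008-0.15 Hz slow-wave band.
#' @return A filtered [egg_recording()] at the same sampling rate.
#' @export
extract_egg <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "egg_recording"), inherits(spec, "filter_spec"))
  if (spec$low_hz >= rec$fs_hz / 2)
    stop_invalid("pass band lies entirely above Nyquist (%g Hz)", rec$fs_hz / 2)
  fun <- switch(spec$method,
                butterworth = bandpass_butter,
                zero_phase_inverse_butterworth = bandstop_complement,
                ib_dct = dct_mask_filter)
  out <- rec$data
  for (ch in which(grepl("^A[1-4]$", rec$channels)))
    out[, ch] <- fun(rec$data[, ch], rec$fs_hz, spec$low_hz, spec$high_hz)
  egg_recording(out, rec$fs_hz, rec$channels, rec$meta)
}

#' Anti-alias filter and downsample a recording to 4 Hz
#'
#' Recordings sampled above 4 Hz are low-pass filtered with a zero-phase
#' 4th-order Butterworth filter (cut-off 2.0 Hz) and decimated to 4 Hz.
#' Integer decimation factors pick every (fs/4)-th sample; non-integer
#' factors (e.g. 250 Hz) use polyphase rational resampling. A 4 Hz
#' recording is returned unchanged.
#'
#' @param rec An [egg_recording()].
#' @param target_fs_hz Output rate, default 4 Hz.
#' @param cutoff_hz Anti-alias cut-off, default 2.0 Hz.
#' @return An [egg_recording()] at `target_fs_hz`.
#' @export
antialias_downsample <- function(rec, target_fs_hz = 4, cutoff_hz = 2.0) {
  stopifnot(inherits(rec, "egg_recording"))
  fs <- rec$fs_hz
  if (fs < target_fs_hz) stop_invalid("fs (%g Hz) below target (%g Hz)", fs, target_fs_hz)
  if (fs == target_fs_hz) return(rec)
  flt <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
  filtered <- apply(rec$data, 2L, function(x) signal::filtfilt(flt, x))
  fac <- fs / target_fs_hz
  if (abs(fac - round(fac)) < 1e-9) {
    idx <- seq(1L, nrow(filtered), by = as.integer(round(fac)))
    out <- filtered[idx, , drop = FALSE]
  } else {
    out <- apply(filtered, 2L, function(x)
      signal::resample(x, p = target_fs_hz, q = fs))
  }
  meta <- rec$meta
  meta$fs_hz <- target_fs_hz
  egg_recording(out, target_fs_hz, rec$channels, meta)
}

#' Artifact mask constructor
#'
#' @param flags Logical vector, one flag per consecutive
#'   `segment_len_s`-second tile (`TRUE` = excluded).
#' @param segment_len_s Tile length in seconds.
#' @param method `1`, `2` or `"manual"` / `"combined"`.
#' @param threshold Threshold multiplier used (or `NA`).
#' @return An `egg_artifact_mask`.
#' @export
artifact_mask <- function(flags, segment_len_s, method = "manual", threshold = NA_real_) {
  structure(list(flags = as.logical(flags), segment_len_s = segment_len_s,
                 method = method, threshold = threshold),
            class = "egg_artifact_mask")
}

#' @export
print.egg_artifact_mask <- function(x, ...) {
  cat(sprintf("<egg_artifact_mask> %d/%d segments flagged (%g s tiles, method %s, threshold %s)\n",
              sum(x$flags), length(x$flags), x$segment_len_s,
              format(x$method), format(x$threshold)))
  invisible(x)
}

#' Detect artifact segments by standard-deviation thresholding
#'
#' The channel is tiled into consecutive `segment_len_s`-second segments and
#' the sample standard deviation of each tile is computed. The artifact
#' limit is `mean(per-segment SD) * threshold`. Method 1 flags a segment if
#' the absolute value of any sample in it exceeds the limit (default
#' threshold 4.2); Method 2 flags a segment if its own SD exceeds the limit
#' (default threshold 1.6). Comparisons are strict, so an all-zero signal
#' produces no flags.
#'
#' @param x Numeric vector: one channel of the band-passed EGG (mV).
#' @param fs Sampling frequency in Hz.
#' @param segment_len_s Tile length in seconds (default 240, the analysis
#'   segment length, so excluded tiles align with analysis segments).
#' @param method `1` (amplitude test) or `2` (SD test).
#' @param threshold Positive multiplier; defaults 4.2 (Method 1) / 1.6
#'   (Method 2).
#' @return An [artifact_mask()].
#' @export
detect_artifacts <- function(x, fs, segment_len_s = 240, method = 1,
                             threshold = if (method == 1) 4.2 else 1.6) {
  if (!method %in% c(1, 2)) stop_invalid("artifact method must be 1 or 2")
  if (!is.numeric(threshold) || threshold <= 0)
    stop_invalid("artifact threshold must be > 0 (got %s)", format(threshold))
  seg_n <- as.integer(round(segment_len_s * fs))
  n_seg <- length(x) %/% seg_n
  if (n_seg < 1L) stop_invalid("signal shorter than one %g s segment", segment_len_s)
  sds <- vapply(seq_len(n_seg), function(i) {
    seg <- x[((i - 1L) * seg_n + 1L):(i * seg_n)]
    if (length(seg) > 1L) stats::sd(seg) else 0
  }, numeric(1))
  limit <- mean(sds) * threshold
  flags <- vapply(seq_len(n_seg), function(i) {
    seg <- x[((i - 1L) * seg_n + 1L):(i * seg_n)]
    if (method == 1) any(abs(seg) > limit) else sds[i] > limit
  }, logical(1))
  artifact_mask(flags, segment_len_s, method = method, threshold = threshold)
}

#' Combine per-channel artifact masks and manual exclusions
#'
#' A segment flagged in any channel is excluded in all channels (logical OR
#' across masks). Manual exclusion intervals, given in minutes, flag every
#' segment they overlap; intervals reaching outside the recording are
#' clipped with a warning.
#'
#' @param masks List of [artifact_mask()] objects on a shared segment grid
#'   (may be empty).
#' @param manual_intervals_min Optional list of `c(start_min, end_min)`
#'   pairs (or a 2-column matrix).
#' @param n_segments,segment_len_s Grid geometry; required when `masks` is
#'   empty, otherwise taken from the first mask.
#' @return A combined [artifact_mask()].
#' @export
combine_masks <- function(masks = list(), manual_intervals_min = NULL,
                          n_segments = NULL, segment_len_s = NULL) {
  if (length(masks) > 0L) {
    segment_len_s <- masks[[1]]$segment_len_s
    n_segments <- length(masks[[1]]$flags)
    for (m in masks) {
      if (length(m$flags) != n_segments || m$segment_len_s != segment_len_s)
        stop_invalid("artifact masks do not share a segment grid")
    }
    flags <- Reduce(`|`, lapply(masks, `[[`, "flags"))
  } else {
    if (is.null(n_segments) || is.null(segment_len_s))
      stop_invalid("grid geometry required when no masks are supplied")
    flags <- rep(FALSE, n_segments)
  }
  if (!is.null(manual_intervals_min)) {
    if (is.matrix(manual_intervals_min))
      manual_intervals_min <- asplit(manual_intervals_min, 1L)
    total_s <- n_segments * segment_len_s
    starts <- (seq_len(n_segments) - 1L) * segment_len_s
    ends <- starts + segment_len_s
    for (iv in manual_intervals_min) {
      a <- iv[1] * 60; b <- iv[2] * 60
      if (a < 0 || b > total_s) {
        warning(sprintf("manual interval (%g, %g) min reaches outside the recording; clipped",
                        iv[1], iv[2]))
        a <- max(a, 0); b <- min(b, total_s)
      }
      # closed-interval overlap: an exclusion touching a tile boundary flags
      # both adjacent tiles (conservative)
      if (b > a) flags <- flags | (starts <= b & ends >= a)
    }
  }
  artifact_mask(flags, segment_len_s, method = "combined")
}

# internal: TRUE if the analysis window [t0, t1) overlaps any flagged tile
mask_excludes <- function(mask, t0, t1) {
  if (is.null(mask) || !any(mask$flags)) return(FALSE)
  starts <- (which(mask$flags) - 1L) * mask$segment_len_s
  any(starts < t1 & (starts + mask$segment_len_s) > t0)
}
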