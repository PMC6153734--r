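# The in-memory representation of a multi-channel EGG recording.
# Amplitudes are always held in mV; integer ADC counts exist only at the
# file boundary (see read_egg_ascii / write_egg_ascii).

#' Construct an EGG recording object
#'
#' Container for a multi-channel electrogastrogram: a sample matrix in mV
#' (one column per channel), the sampling frequency, channel labels and the
#' header metadata carried by the ASCII file format.
#'
#' @param data Numeric matrix, samples x channels, amplitudes in mV.
#' @param fs_hz Sampling frequency in Hz (>= 4).
#' @param channels Character vector of channel labels; defaults to
#'   `A1..A<k>` with a trailing `"sensor"` when a fifth column is present.
#' @param meta A header-metadata list as returned by [parse_egg_header()];
#'   a minimal default is constructed when omitted.
#' @return An object of class `egg_recording` with elements `data`, `fs_hz`,
#'   `channels`, `meta`.
#' @seealso [read_egg_ascii()], [synth_egg_recording()]
#' @export
egg_recording <- function(data, fs_hz, channels = NULL, meta = NULL) {
  if (is.null(dim(data))) data <- matrix(data, ncol = 1L)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop_invalid("recording amplitudes must be finite")
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz < 4)
    stop_invalid("sampling frequency must be a single number >= 4 Hz (got %s)",
                 format(fs_hz))
  nch <- ncol(data)
  if (is.null(channels)) {
    channels <- if (nch <= 4L) paste0("A", seq_len(nch))
                else c(paste0("A", 1:4), "sensor")[seq_len(nch)]
  }
  if (length(channels) != nch)
    stop_invalid("%d channel labels for %d data columns", length(channels), nch)
  colnames(data) <- channels
  if (is.null(meta)) {
    meta <- list(patient_label = "", meal_type = "", meal_start_s = 0,
                 meal_end_s = 0, fs_hz = fs_hz, adc_bits = NA_integer_,
                 counts_per_mv = 1)
  }
  validate_header_meta(meta)
  if (!isTRUE(all.equal(meta$fs_hz, fs_hz)))
    stop_invalid("header fs (%g Hz) disagrees with recording fs (%g Hz)",
                 meta$fs_hz, fs_hz)
  structure(list(data = data, fs_hz = fs_hz, channels = channels, meta = meta),
            class = "egg_recording")
}

#' @export
print.egg_recording <- function(x, ...) {
  dur <- nrow(x$data) / x$fs_hz
  cat(sprintf("<egg_recording> %d channel(s) [%s], %d samples @ %g Hz (%.1f min)\n",
              ncol(x$data), paste(x$channels, collapse = ", "),
              nrow(x$data), x$fs_hz, dur / 60))
  if (x$meta$meal_end_s > x$meta$meal_start_s)
    cat(sprintf("  meal: %g-%g s\n", x$meta$meal_start_s, x$meta$meal_end_s))
  invisible(x)
}

#' @export
plot.egg_recording <- function(x, channels = x$channels, t_range_s = NULL, ...) {
  t <- (seq_len(nrow(x$data)) - 1) / x$fs_hz
  keep <- if (is.null(t_range_s)) rep(TRUE, length(t))
          else t >= t_range_s[1] & t <= t_range_s[2]
  idx <- match(channels, x$channels)
  old <- graphics::par(mfrow = c(length(idx), 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(old))
  for (i in idx)
    graphics::plot(t[keep], x$data[keep, i], type = "l",
                   xlab = "time [s]", ylab = paste0(x$channels[i], " [mV]"), ...)
  invisible(x)
}

#' Number of EGG channels in a recording
#'
#' Counts the electrogastrogram channels (labels `A1..A4`), excluding any
#' auxiliary sensor channel.
#' @param rec An `egg_recording`.
#' @return Integer count (1-4).
#' @export
n_egg_channels <- function(rec) {
  sum(grepl("^A[1-4]$", rec$channels))
}

#' Extract the EGG channel columns of a recording as a matrix
#' @param rec An `egg_recording`.
#' @return Numeric matrix with one column per EGG channel (mV).
#' @export
egg_channel_matrix <- function(rec) {
  rec$data[, grepl("^A[1-4]$", rec$channels), drop = FALSE]
}

# internal: duration in seconds
rec_duration_s <- function(rec) nrow(rec$data) / rec$fs_hz
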