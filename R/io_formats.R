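# Reader/writer for the 8-row-header ASCII EGG interchange format and
# serializers for analysis results.
#
# Header layout (by row position; keywords are tolerated but not required):
#   1  patient label (free text, may be empty)
#   2  meal type / code (free text, may be empty)
#   3  meal start time in seconds        e.g. "start: 1800"
#   4  meal end time in seconds          e.g. "stop: 2100"
#   5  sampling frequency in Hz (>= 4)   e.g. "Fs= 250 Hz"
#   6  A/D resolution in bits (optional) e.g. "AD= 24 bits"
#   7  ADC counts per 1 mV               e.g. "1mV= 20970"
#   8  empty / ignored
# Sample data start on line 9: space-separated integer counts, one row per
# sample, columns ordered A1 A2 A3 A4 sensor (trailing columns may be absent).

# internal: the value of a header line. Keyword rows carry the number after
# a "=" or ":" separator ("Fs= 250 Hz", "1mV= 20970" -- the leading "1" of
# "1mV" is part of the keyword, not the value); bare rows carry it directly.
first_number <- function(line) {
  sep <- regexpr("[=:]", line)
  if (sep > 0L) line <- substring(line, sep + 1L)
  m <- regmatches(line, regexpr("[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?", line))
  if (length(m) == 0L) NA_real_ else as.numeric(m)
}

validate_header_meta <- function(meta) {
  if (!is.finite(meta$fs_hz) || meta$fs_hz < 4)
    stop_invalid("sampling frequency must be >= 4 Hz (got %s)", format(meta$fs_hz))
  if (!is.finite(meta$counts_per_mv) || meta$counts_per_mv <= 0)
    stop_invalid("counts-per-mV scale must be > 0 (got %s)",
                 format(meta$counts_per_mv))
  if (meta$meal_end_s < meta$meal_start_s)
    stop_invalid("meal end (%g s) precedes meal start (%g s)",
                 meta$meal_end_s, meta$meal_start_s)
  if (meta$meal_start_s < 0) stop_invalid("meal start must be >= 0 s")
  invisible(meta)
}

#' Parse the 8-row header of an ASCII EGG file
#'
#' Rows are interpreted by position. Rows 3 (meal start, s), 4 (meal end, s),
#' 5 (sampling frequency, Hz) and 7 (counts per 1 mV) must contain a number;
#' rows 1, 2 and 6 are free text and may be empty; row 8 is ignored.
#'
#' @param lines Character vector: exactly the first 8 lines of the file.
#' @return A list with elements `patient_label`, `meal_type`, `meal_start_s`,
#'   `meal_end_s`, `fs_hz`, `adc_bits` (integer or `NA`), `counts_per_mv`.
#' @export
parse_egg_header <- function(lines) {
  if (length(lines) != 8L)
    stop_format("header must be exactly 8 lines (got %d)", length(lines))
  num <- vapply(lines, first_number, numeric(1), USE.NAMES = FALSE)
  if (!is.finite(num[3])) stop_format("header row 3 (meal start) has no number: '%s'", lines[3])
  if (!is.finite(num[4])) stop_format("header row 4 (meal end) has no number: '%s'", lines[4])
  if (!is.finite(num[5])) stop_format("header row 5 (sampling frequency) has no number: '%s'", lines[5])
  if (!is.finite(num[7])) stop_format("header row 7 (1mV scale) has no number: '%s'", lines[7])
  meta <- list(patient_label = trimws(lines[1]),
               meal_type = trimws(lines[2]),
               meal_start_s = num[3],
               meal_end_s = num[4],
               fs_hz = num[5],
               adc_bits = if (is.finite(num[6])) as.integer(num[6]) else NA_integer_,
               counts_per_mv = num[7])
  validate_header_meta(meta)
  meta
}

#' Read an ASCII EGG file
#'
#' Parses the 8-row header, then reads space-separated integer samples from
#' line 9 on and converts them to mV by dividing by the counts-per-mV scale.
#' Columns are taken in the fixed order A1 A2 A3 A4 sensor. When fewer than
#' 4 EGG columns are present, channel A1 is replicated into the missing EGG
#' channels so that downstream analysis always sees 4 EGG channels.
#'
#' @param path Path to the file.
#' @param replicate_channels Replicate A1 into missing EGG channels
#'   (default `TRUE`, matching the format contract).
#' @return An [egg_recording()] with amplitudes in mV.
#' @export
read_egg_ascii <- function(path, replicate_channels = TRUE) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 9L)
    stop_format("file has %d lines; need 8 header lines plus data", length(lines))
  meta <- parse_egg_header(lines[1:8])
  data_lines <- lines[-(1:8)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) == 0L) stop_format("no sample rows after header")
  toks <- strsplit(trimws(data_lines), "[ \t]+")
  ncols <- lengths(toks)
  if (any(ncols != ncols[1])) {
    bad <- which(ncols != ncols[1])[1]
    stop_format("ragged sample row at line %d: %d columns, expected %d",
                bad + 8L, ncols[bad], ncols[1])
  }
  vals <- suppressWarnings(as.numeric(unlist(toks, use.names = FALSE)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop_format("non-numeric sample token near line %d",
                ((bad - 1) %/% ncols[1]) + 9L)
  }
  counts <- matrix(vals, ncol = ncols[1], byrow = TRUE)
  nc <- ncol(counts)
  if (nc > 5L) stop_format("at most 5 data columns supported (got %d)", nc)
  n_egg <- min(nc, 4L)
  labels <- c(paste0("A", seq_len(n_egg)), if (nc == 5L) "sensor")
  mv <- counts / meta$counts_per_mv
  colnames(mv) <- labels
  if (replicate_channels && n_egg < 4L) {
    sensor <- if (nc == 5L) mv[, "sensor", drop = FALSE] else NULL
    eggm <- mv[, seq_len(n_egg), drop = FALSE]
    extra <- matrix(rep(eggm[, 1], 4L - n_egg), ncol = 4L - n_egg)
    colnames(extra) <- paste0("A", (n_egg + 1L):4L)
    mv <- cbind(eggm, extra, sensor)
  }
  egg_recording(mv, fs_hz = meta$fs_hz, channels = colnames(mv), meta = meta)
}

#' Write a recording to the ASCII EGG format
#'
#' Emits the 8-row header followed by space-separated integer counts
#' (`round(mV * counts_per_mv)`) from line 9. Samples whose scaled value
#' exceeds the ADC range implied by `adc_bits` are clipped with a warning.
#'
#' @param rec An [egg_recording()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_egg_ascii <- function(rec, path) {
  meta <- rec$meta
  header <- c(meta$patient_label,
              meta$meal_type,
              sprintf("start: %g", meta$meal_start_s),
              sprintf("stop: %g", meta$meal_end_s),
              sprintf("Fs= %g Hz", meta$fs_hz),
              if (is.na(meta$adc_bits)) "" else sprintf("AD= %d bits", meta$adc_bits),
              sprintf("1mV= %g", meta$counts_per_mv),
              "")
  counts <- round(rec$data * meta$counts_per_mv)
  if (!is.na(meta$adc_bits)) {
    lim <- c(-2^(meta$adc_bits - 1), 2^(meta$adc_bits - 1) - 1)
    if (any(counts < lim[1] | counts > lim[2])) {
      warning(sprintf("samples exceed the %d-bit ADC range; clipping", meta$adc_bits))
      counts <- pmin(pmax(counts, lim[1]), lim[2])
    }
  }
  body <- apply(counts, 1L, function(r) paste(format(r, scientific = FALSE, trim = TRUE),
                                              collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Export analysis results to CSV, JSON or a plain-text report
#'
#' Serializes the bundle produced by [run_analysis()]. CSV writes one table
#' per result family (`<stem>_segments.csv`, `<stem>_periods.csv`, and when
#' present `<stem>_swc.csv`, `<stem>_hrv.csv`); JSON writes a single nested
#' file; text writes a human-readable per-period summary. When `path` is a
#' directory, the output stem embeds the source recording's name and a
#' timestamp.
#'
#' @param results A results bundle from [run_analysis()].
#' @param path Output file path, or an existing directory (auto-named).
#' @param format `"csv"`, `"json"` or `"text"`.
#' @return Invisibly, the path(s) written.
#' @export
export_results <- function(results, path, format = c("csv", "json", "text")) {
  format <- match.arg(format)
  stem_name <- function(ext) {
    src <- sub("\\.[^.]*$", "", basename(results$source %||% "analysis"))
    file.path(path, sprintf("%s_%s.%s", src,
                            format(Sys.time(), "%Y%m%d_%H%M%S"), ext))
  }
  if (dir.exists(path)) {
    path <- stem_name(switch(format, csv = "csv", json = "json", text = "txt"))
  }
  out <- character(0)
  if (format == "json") {
    jsonlite::write_json(results_to_list(results), path,
                         auto_unbox = TRUE, digits = NA, null = "null", na = "null")
    out <- path
  } else if (format == "csv") {
    stem <- sub("\\.csv$", "", path)
    utils::write.csv(results$rsa$segments, paste0(stem, "_segments.csv"),
                     row.names = FALSE)
    utils::write.csv(results$parameters$periods, paste0(stem, "_periods.csv"),
                     row.names = FALSE)
    out <- paste0(stem, c("_segments.csv", "_periods.csv"))
    if (!is.null(results$parameters$swc)) {
      utils::write.csv(results$parameters$swc, paste0(stem, "_swc.csv"),
                       row.names = FALSE)
      out <- c(out, paste0(stem, "_swc.csv"))
    }
    if (!is.null(results$hrv)) {
      utils::write.csv(results$hrv$freq$windows, paste0(stem, "_hrv.csv"),
                       row.names = FALSE)
      out <- c(out, paste0(stem, "_hrv.csv"))
    }
  } else {
    writeLines(results_text_report(results), path)
    out <- path
  }
  invisible(out)
}

# internal: JSON-serializable view of a results bundle
results_to_list <- function(results) {
  cfg <- results$config
  cfg$filter <- unclass(cfg$filter)
  cfg$rsa <- unclass(cfg$rsa)
  list(source = results$source %||% NA,
       config = unclass(cfg),
       segments = results$rsa$segments,
       periods = results$parameters$periods,
       swc = results$parameters$swc,
       spatial_dp = results$parameters$spatial_dp,
       fed_fast = results$parameters$fed_fast,
       osa = osa_summary(results$osa),
       hrv = if (is.null(results$hrv)) NULL else
         list(time = results$hrv$time, freq_summary = results$hrv$freq$summary,
              freq_windows = results$hrv$freq$windows))
}

# internal: plain-text per-period report
results_text_report <- function(results) {
  lines <- c(sprintf("EGG analysis report: %s", results$source %||% "<in-memory>"),
             strrep("=", 60))
  per <- results$parameters$periods
  for (p in unique(per$period)) {
    lines <- c(lines, "", sprintf("Period: %s", p), strrep("-", 40))
    sub <- per[per$period == p, ]
    for (i in seq_len(nrow(sub))) {
      r <- sub[i, ]
      lines <- c(lines, sprintf(
        "  %s  DF %.2f cpm (sd %.2f)  DP %.1f dB  NI %.1f%%  brady %.1f%%  tachy %.1f%%  arrhythmia %.1f%%",
        r$channel, r$df_mean_cpm, r$df_sd_cpm, r$dp_mean_db,
        r$pct_normo, r$pct_brady, r$pct_tachy, r$pct_arrhythmia))
    }
    osum <- osa_summary(results$osa)
    osum <- osum[osum$period == p & osum$computable, , drop = FALSE]
    for (i in seq_len(nrow(osum))) {
      q <- osum[i, ]
      lines <- c(lines, sprintf(
        "  overall %s: ODF %.2f cpm  ODP %.1f dB  power %% (brady/normo/tachy) %.1f/%.1f/%.1f",
        q$channel, q$odf_cpm, q$odp_db, q$brady_pct, q$normo_pct, q$tachy_pct))
    }
  }
  lines
}
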