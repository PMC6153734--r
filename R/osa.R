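# Overall Spectrum Analysis (OSA): averaged PSDs per examination period and
# for the whole examination, overall dominant frequency/power (ODF/ODP) and
# the band power distribution.

#' Build the examination period plan
#'
#' Splits the examination into a pre-prandial period `[0, meal_start)`, the
#' meal `[meal_start, meal_end)`, and consecutive 30-minute postprandial
#' periods; a trailing partial period is kept when it still holds at least
#' one OSA segment. Meal times `(0, 0)` yield a single period spanning the
#' whole recording.
#'
#' @param meta Header metadata (needs `meal_start_s`, `meal_end_s`).
#' @param total_duration_s Recording duration in seconds.
#' @param post_period_s Postprandial period length, default 1800 s.
#' @param min_period_s Shortest period worth keeping, default 240 s (one
#'   4-minute OSA segment).
#' @return Data frame of class `egg_period_plan` with columns `label`,
#'   `t_start_s`, `t_end_s`, `is_meal`.
#' @export
build_period_plan <- function(meta, total_duration_s, post_period_s = 1800,
                              min_period_s = 240) {
  ms <- meta$meal_start_s
  me <- meta$meal_end_s
  if (me > total_duration_s)
    stop_invalid("meal end (%g s) beyond the recording (%g s)", me,
                 total_duration_s)
  rows <- list()
  add <- function(label, a, b, is_meal = FALSE)
    rows[[length(rows) + 1L]] <<- data.frame(label = label, t_start_s = a,
                                             t_end_s = b, is_meal = is_meal,
                                             stringsAsFactors = FALSE)
  if (ms == 0 && me == 0) {
    add("all", 0, total_duration_s)
  } else {
    if (ms > 0) add("preprandial", 0, ms)
    if (me > ms) add("meal", ms, me, is_meal = TRUE)
    k <- 1L
    t0 <- me
    while (t0 < total_duration_s) {
      t1 <- min(t0 + post_period_s, total_duration_s)
      if (t1 - t0 >= min_period_s || k == 1L) {
        if (t1 - t0 >= min_period_s) add(sprintf("postprandial-%d", k), t0, t1)
        k <- k + 1L
      }
      t0 <- t1
    }
  }
  plan <- do.call(rbind, rows)
  class(plan) <- c("egg_period_plan", class(plan))
  plan
}

#' Average power spectral densities
#'
#' Pointwise arithmetic mean of linear PSDs on a shared frequency grid.
#'
#' @param spectra Non-empty list of `egg_spectrum` objects.
#' @return An `egg_spectrum`.
#' @export
average_psd <- function(spectra) {
  if (length(spectra) == 0L) stop_invalid("no spectra to average")
  f <- spectra[[1]]$freq_cpm
  for (s in spectra)
    if (length(s$freq_cpm) != length(f) || any(abs(s$freq_cpm - f) > 1e-9))
      stop_invalid("spectra do not share a frequency grid")
  m <- rowMeans(vapply(spectra, `[[`, numeric(length(f)), "psd"))
  egg_spectrum(f, m, method = paste0("mean_of_", length(spectra)),
               meta = list(n = length(spectra)))
}

# internal: trapezoidal integral of (f, p) over [a, b] with interpolated edges
integrate_band <- function(f, p, a, b) {
  if (b <= a) return(0)
  inside <- f > a & f < b
  fa <- stats::approx(f, p, xout = a, rule = 2)$y
  fb <- stats::approx(f, p, xout = b, rule = 2)$y
  ff <- c(a, f[inside], b)
  pp <- c(fa, p[inside], fb)
  pracma::trapz(ff, pp)
}

#' Percentage distribution of EGG power over the rhythm bands
#'
#' Integrates the linear PSD over the bradygastria `[0.5, normo_low)`,
#' normogastria `[normo_low, normo_high]` and tachygastria
#' `(normo_high, 9]` cpm bands (trapezoidal rule) and reports each as a
#' percentage of the total 0.5-9 cpm power.
#'
#' @param spec An `egg_spectrum`.
#' @param normo_cpm Normogastria band, default `c(2, 4)`.
#' @param df_range_cpm Full EGG band, default `c(0.5, 9)`.
#' @return Named numeric vector `c(brady, normo, tachy)` in percent.
#' @export
band_power_distribution <- function(spec, normo_cpm = c(2, 4),
                                    df_range_cpm = c(0.5, 9)) {
  f <- spec$freq_cpm
  p <- spec$psd
  if (max(f) < df_range_cpm[2])
    stop_invalid("spectrum does not cover %g cpm", df_range_cpm[2])
  brady <- integrate_band(f, p, df_range_cpm[1], normo_cpm[1])
  normo <- integrate_band(f, p, normo_cpm[1], normo_cpm[2])
  tachy <- integrate_band(f, p, normo_cpm[2], df_range_cpm[2])
  total <- brady + normo + tachy
  if (total <= 0) stop_invalid("no in-band power between %g and %g cpm",
                               df_range_cpm[1], df_range_cpm[2])
  c(brady = brady, normo = normo, tachy = tachy) / total * 100
}

# internal: OSA segment geometry per method
osa_geometry <- function(method) {
  switch(method,
    periodogram4 = list(lseg_s = 240, sseg_s = 120),
    ar4 = list(lseg_s = 240, sseg_s = 120),
    ar1 = list(lseg_s = 60, sseg_s = 10))
}

# internal: per-segment PSD estimator per OSA method
osa_psd <- function(samples, fs, method, lspv) {
  switch(method,
    periodogram4 = psd_periodogram(samples, fs, "tukey", lspv),
    ar4 = psd_ar(samples, fs, lspv = lspv),
    ar1 = psd_ar(samples, fs, lspv = lspv))
}

# internal: analyze one period of one channel; returns result + segment PSDs
osa_period <- function(x, fs, t0, t1, mask, method, lspv, normo_cpm,
                       df_range_cpm) {
  geo <- osa_geometry(method)
  i0 <- as.integer(round(t0 * fs)) + 1L
  i1 <- min(as.integer(round(t1 * fs)), length(x))
  seg <- x[i0:i1]
  not_computable <- function(reason)
    list(computable = FALSE, reason = reason, n_segments = 0L,
         spectrum = NULL, odf_cpm = NA_real_, odp_db = NA_real_,
         corrected = FALSE, arrhythmia = FALSE,
         band_power_pct = c(brady = NA_real_, normo = NA_real_,
                            tachy = NA_real_), psds = list())
  if (length(seg) < geo$lseg_s * fs) return(not_computable("period shorter than one segment"))
  pieces <- segment_signal(seg, fs, geo$lseg_s, geo$sseg_s)
  psds <- list()
  for (p in pieces) {
    abs_t0 <- t0 + p$t_start_s
    if (mask_excludes(mask, abs_t0, abs_t0 + geo$lseg_s)) next
    psds[[length(psds) + 1L]] <- osa_psd(p$samples, fs, method, lspv)
  }
  if (length(psds) == 0L) return(not_computable("all segments excluded"))
  avg <- average_psd(psds)
  dom <- find_dominant(avg, df_range_cpm)
  list(computable = TRUE, reason = NA_character_, n_segments = length(psds),
       spectrum = avg, odf_cpm = dom$df_cpm, odp_db = dom$dp_db,
       corrected = dom$corrected, arrhythmia = dom$arrhythmia,
       band_power_pct = band_power_distribution(avg, normo_cpm, df_range_cpm),
       psds = psds)
}

#' Run the Overall Spectrum Analysis
#'
#' For every EGG channel, segments each period of the plan (segment grids
#' restart at the period start: 240 s / 120 s overlap for `periodogram4`
#' and `ar4`, 60 s / 10 s overlap for `ar1`), estimates one PSD per
#' non-excluded segment, averages them per period, and derives the overall
#' dominant frequency and power (same dominant-peak rule as the RSA) plus
#' the band power distribution. The whole-examination spectrum averages all
#' segment PSDs of the non-meal periods (the meal period is skipped by
#' default: chewing and movement make it uninterpretable).
#'
#' @param rec An [egg_recording()] at 4 Hz (band-passed).
#' @param mask Optional combined [artifact_mask()].
#' @param plan An `egg_period_plan`; built from the header when `NULL`.
#' @param method `"periodogram4"` (default), `"ar4"` or `"ar1"`.
#' @param lspv One-sided spectral samples, default 4096.
#' @param normo_cpm,df_range_cpm Rhythm bands in cpm.
#' @param include_meal Average the meal period like any other (default
#'   `FALSE`).
#' @return List of class `egg_osa`: `method`, `plan`, and `channels`, a
#'   per-channel list each holding `periods` (per-period result lists) and
#'   `whole`.
#' @export
run_osa <- function(rec, mask = NULL, plan = NULL,
                    method = c("periodogram4", "ar4", "ar1"), lspv = 4096,
                    normo_cpm = c(2, 4), df_range_cpm = c(0.5, 9),
                    include_meal = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(rec, "egg_recording"))
  if (is.null(plan)) plan <- build_period_plan(rec$meta, rec_duration_s(rec))
  ch_idx <- which(grepl("^A[1-4]$", rec$channels))
  channels <- list()
  for (ci in ch_idx) {
    x <- rec$data[, ci]
    periods <- list()
    all_psds <- list()
    for (pi in seq_len(nrow(plan))) {
      row <- plan[pi, ]
      if (row$is_meal && !include_meal) {
        res <- list(computable = FALSE, reason = "meal period excluded",
                    n_segments = 0L, spectrum = NULL, odf_cpm = NA_real_,
                    odp_db = NA_real_, corrected = FALSE, arrhythmia = FALSE,
                    band_power_pct = c(brady = NA_real_, normo = NA_real_,
                                       tachy = NA_real_), psds = list())
      } else {
        res <- osa_period(x, rec$fs_hz, row$t_start_s, row$t_end_s, mask,
                          method, lspv, normo_cpm, df_range_cpm)
      }
      all_psds <- c(all_psds, res$psds)
      res$psds <- NULL
      res$label <- row$label
      res$t_start_s <- row$t_start_s
      res$t_end_s <- row$t_end_s
      periods[[row$label]] <- res
    }
    whole <- if (length(all_psds) > 0L) {
      avg <- average_psd(all_psds)
      dom <- find_dominant(avg, df_range_cpm)
      list(computable = TRUE, n_segments = length(all_psds), spectrum = avg,
           odf_cpm = dom$df_cpm, odp_db = dom$dp_db, corrected = dom$corrected,
           arrhythmia = dom$arrhythmia,
           band_power_pct = band_power_distribution(avg, normo_cpm, df_range_cpm))
    } else {
      list(computable = FALSE, n_segments = 0L, spectrum = NULL,
           odf_cpm = NA_real_, odp_db = NA_real_, corrected = FALSE,
           arrhythmia = FALSE,
           band_power_pct = c(brady = NA_real_, normo = NA_real_,
                              tachy = NA_real_))
    }
    channels[[rec$channels[ci]]] <- list(periods = periods, whole = whole)
  }
  structure(list(method = method, plan = plan, channels = channels),
            class = "egg_osa")
}

#' Tabular summary of an OSA result
#'
#' @param osa An `egg_osa` from [run_osa()].
#' @return Data frame with one row per channel per period (plus a `whole`
#'   row per channel): ODF, ODP and band power percentages.
#' @export
osa_summary <- function(osa) {
  rows <- list()
  for (ch in names(osa$channels)) {
    entry <- osa$channels[[ch]]
    items <- c(entry$periods, list(whole = entry$whole))
    for (lbl in names(items)) {
      p <- items[[lbl]]
      rows[[length(rows) + 1L]] <- data.frame(
        channel = ch, period = lbl, computable = p$computable,
        n_segments = p$n_segments, odf_cpm = p$odf_cpm, odp_db = p$odp_db,
        arrhythmia = p$arrhythmia,
        brady_pct = p$band_power_pct[["brady"]],
        normo_pct = p$band_power_pct[["normo"]],
        tachy_pct = p$band_power_pct[["tachy"]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
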