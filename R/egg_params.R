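# Clinically established gastric-rhythm parameters derived from the RSA
# segment results: rhythm-class percentages (normogastria index), DF/DP
# statistics, instability coefficients, maximum DF difference, slow-wave
# coupling between channel pairs, spatial dominant-power difference, and the
# fed/fast power ratio from the OSA.

# internal: sample sd with the n = 1 -> 0 convention
sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

#' Rhythm-class percentages (normogastria index and dysrhythmias)
#'
#' Counts of bradygastric / normogastric / tachygastric / arrhythmic
#' segments over all included (non-excluded) segments, as percentages.
#' The normogastria percentage is the normogastria index (NI).
#'
#' @param segments Data frame of RSA segment rows (one channel).
#' @return Named vector `c(brady, normo, tachy, arrhythmia)` in percent,
#'   or all-`NA` when no segment is included.
#' @export
rhythm_percentages <- function(segments) {
  inc <- segments[!segments$excluded, , drop = FALSE]
  out <- c(brady = NA_real_, normo = NA_real_, tachy = NA_real_,
           arrhythmia = NA_real_)
  if (nrow(inc) == 0L) return(out)
  n <- nrow(inc)
  c(brady = sum(inc$rhythm == "bradygastria"),
    normo = sum(inc$rhythm == "normogastria"),
    tachy = sum(inc$rhythm == "tachygastria"),
    arrhythmia = sum(inc$rhythm == "arrhythmia")) / n * 100
}

#' Mean, median and standard deviation of DF and DP
#'
#' Statistics over the included, non-arrhythmic segments (arrhythmic
#' segments carry no DF/DP). DF in cpm, DP in dB.
#'
#' @param segments Data frame of RSA segment rows (one channel).
#' @return Named list of `df_mean_cpm`, `df_median_cpm`, `df_sd_cpm`,
#'   `dp_mean_db`, `dp_median_db`, `dp_sd_db`, `n_used`; all `NA` when no
#'   segment is usable.
#' @export
df_dp_statistics <- function(segments) {
  use <- segments[!segments$excluded & !is.na(segments$df_cpm), , drop = FALSE]
  if (nrow(use) == 0L)
    return(list(df_mean_cpm = NA_real_, df_median_cpm = NA_real_,
                df_sd_cpm = NA_real_, dp_mean_db = NA_real_,
                dp_median_db = NA_real_, dp_sd_db = NA_real_, n_used = 0L))
  list(df_mean_cpm = mean(use$df_cpm), df_median_cpm = stats::median(use$df_cpm),
       df_sd_cpm = sd0(use$df_cpm), dp_mean_db = mean(use$dp_db),
       dp_median_db = stats::median(use$dp_db), dp_sd_db = sd0(use$dp_db),
       n_used = nrow(use))
}

#' Frequency and power instability coefficients
#'
#' Coefficients of variation across the usable segments: FIC = sd(DF) /
#' mean(DF); PIC = sd(P) / mean(P) with P the dominant power. PIC is
#' computed on the linear power by default (the coefficient of variation of
#' dB values is not invariant to rescaling); set `pic_scale = "db"` for
#' compatibility with systems that use the dB series.
#'
#' @param segments Data frame of RSA segment rows (one channel).
#' @param pic_scale `"linear"` (default) or `"db"`.
#' @return List `fic`, `pic` (both `NA` when fewer than 2 usable segments
#'   or zero mean).
#' @export
instability_coefficients <- function(segments, pic_scale = c("linear", "db")) {
  pic_scale <- match.arg(pic_scale)
  use <- segments[!segments$excluded & !is.na(segments$df_cpm), , drop = FALSE]
  if (nrow(use) < 2L) return(list(fic = NA_real_, pic = NA_real_))
  fic <- if (mean(use$df_cpm) == 0) NA_real_
         else sd0(use$df_cpm) / mean(use$df_cpm)
  p <- if (pic_scale == "linear") db_power(use$dp_db) else use$dp_db
  pic <- if (mean(p) == 0) NA_real_ else sd0(p) / mean(p)
  list(fic = fic, pic = pic)
}

#' Maximum dominant frequency difference
#'
#' @param segments Data frame of RSA segment rows (one channel).
#' @return `max(DF) - min(DF)` in cpm over usable segments (`NA` if none;
#'   0 for a single segment).
#' @export
max_df_difference <- function(segments) {
  df <- segments$df_cpm[!segments$excluded & !is.na(segments$df_cpm)]
  if (length(df) == 0L) return(NA_real_)
  max(df) - min(df)
}

#' Percentage of slow-wave coupling between two channels
#'
#' Over segments where both channels carry a DF, the percentage whose
#' dominant frequencies agree within `tol_cpm`.
#'
#' @param seg_a,seg_b RSA segment rows for the two channels, on the same
#'   segment grid.
#' @param tol_cpm Agreement tolerance in cpm, default 0.2.
#' @return Percentage in `[0, 100]`, or `NA` when no segment pair is usable.
#' @export
slow_wave_coupling <- function(seg_a, seg_b, tol_cpm = 0.2) {
  a <- seg_a[order(seg_a$segment), ]
  b <- seg_b[order(seg_b$segment), ]
  common <- intersect(a$segment, b$segment)
  a <- a[match(common, a$segment), ]
  b <- b[match(common, b$segment), ]
  ok <- !a$excluded & !b$excluded & !is.na(a$df_cpm) & !is.na(b$df_cpm)
  if (!any(ok)) return(NA_real_)
  mean(abs(a$df_cpm[ok] - b$df_cpm[ok]) <= tol_cpm) * 100
}

#' Spatial dominant-power difference across channels
#'
#' Difference between the largest and smallest per-channel mean DP (dB)
#' within a period.
#'
#' @param segments RSA segment rows for all channels of one period.
#' @return dB difference, or `NA` with fewer than 2 channels carrying DP.
#' @export
spatial_dp_difference <- function(segments) {
  use <- segments[!segments$excluded & !is.na(segments$dp_db), , drop = FALSE]
  means <- tapply(use$dp_db, use$channel, mean)
  means <- means[!is.na(means)]
  if (length(means) < 2L) return(NA_real_)
  max(means) - min(means)
}

#' Fed/fast (postprandial/pre-prandial) power ratio
#'
#' Linear ratio of the overall dominant powers,
#' `10^((ODP_post - ODP_pre)/10)`, together with the dB difference.
#'
#' @param odp_pre_db,odp_post_db Overall dominant powers in dB.
#' @return List `ratio`, `diff_db` (both `NA` when either input is missing).
#' @export
fed_fast_power_ratio <- function(odp_pre_db, odp_post_db) {
  if (is.na(odp_pre_db) || is.na(odp_post_db))
    return(list(ratio = NA_real_, diff_db = NA_real_))
  d <- odp_post_db - odp_pre_db
  list(ratio = db_power(d), diff_db = d)
}

# internal: assign each RSA segment row to the period containing its start
assign_periods <- function(segments, plan) {
  lbl <- rep(NA_character_, nrow(segments))
  for (i in seq_len(nrow(plan)))
    lbl[segments$t_start_s >= plan$t_start_s[i] &
        segments$t_start_s < plan$t_end_s[i]] <- plan$label[i]
  segments$period <- lbl
  segments
}

#' Compute the full clinical parameter set from RSA results
#'
#' Evaluates every RSA-based parameter per channel, per period and for the
#' whole examination (all periods except the meal): DF/DP statistics,
#' rhythm-class percentages, instability coefficients, maximum DF
#' difference, slow-wave coupling for every channel pair, and the spatial
#' dominant-power difference.
#'
#' @param rsa An `egg_rsa` from [run_rsa()].
#' @param plan An `egg_period_plan`; a single all-spanning period when
#'   `NULL`.
#' @param swc_tol_cpm Slow-wave-coupling tolerance, default 0.2 cpm.
#' @param pic_scale Passed to [instability_coefficients()].
#' @return List of class `egg_parameters`: `periods` (data frame, one row
#'   per channel per period plus `whole`), `swc` (data frame per channel
#'   pair per period), `spatial_dp` (data frame per period).
#' @export
compute_egg_parameters <- function(rsa, plan = NULL, swc_tol_cpm = 0.2,
                                   pic_scale = "linear") {
  segs <- rsa$segments
  if (is.null(plan)) {
    plan <- data.frame(label = "all", t_start_s = 0,
                       t_end_s = max(segs$t_start_s) + rsa$config$lseg_s,
                       is_meal = FALSE, stringsAsFactors = FALSE)
  }
  segs <- assign_periods(segs, plan)
  non_meal <- plan$label[!plan$is_meal]
  scopes <- c(stats::setNames(as.list(plan$label), plan$label),
              list(whole = non_meal))
  channels <- unique(segs$channel)
  per_rows <- list()
  swc_rows <- list()
  sp_rows <- list()
  for (scope in names(scopes)) {
    in_scope <- segs[segs$period %in% scopes[[scope]] & !is.na(segs$period), ,
                     drop = FALSE]
    for (ch in channels) {
      s <- in_scope[in_scope$channel == ch, , drop = FALSE]
      st <- df_dp_statistics(s)
      pc <- rhythm_percentages(s)
      ic <- instability_coefficients(s, pic_scale)
      per_rows[[length(per_rows) + 1L]] <- data.frame(
        period = scope, channel = ch, n_segments = nrow(s),
        n_included = sum(!s$excluded), n_used = st$n_used,
        df_mean_cpm = st$df_mean_cpm, df_median_cpm = st$df_median_cpm,
        df_sd_cpm = st$df_sd_cpm, dp_mean_db = st$dp_mean_db,
        dp_median_db = st$dp_median_db, dp_sd_db = st$dp_sd_db,
        pct_brady = pc[["brady"]], pct_normo = pc[["normo"]],
        pct_tachy = pc[["tachy"]], pct_arrhythmia = pc[["arrhythmia"]],
        fic = ic$fic, pic = ic$pic,
        max_df_diff_cpm = max_df_difference(s),
        stringsAsFactors = FALSE)
    }
    if (length(channels) >= 2L) {
      for (i in seq_along(channels)) for (j in seq_along(channels)) {
        if (j <= i) next
        swc_rows[[length(swc_rows) + 1L]] <- data.frame(
          period = scope, channel_a = channels[i], channel_b = channels[j],
          swc_pct = slow_wave_coupling(
            in_scope[in_scope$channel == channels[i], , drop = FALSE],
            in_scope[in_scope$channel == channels[j], , drop = FALSE],
            swc_tol_cpm),
          stringsAsFactors = FALSE)
      }
      sp_rows[[length(sp_rows) + 1L]] <- data.frame(
        period = scope, spatial_dp_diff_db = spatial_dp_difference(in_scope),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(periods = do.call(rbind, per_rows),
                 swc = if (length(swc_rows)) do.call(rbind, swc_rows),
                 spatial_dp = if (length(sp_rows)) do.call(rbind, sp_rows)),
            class = "egg_parameters")
}
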