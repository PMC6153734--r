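# Pipeline orchestration: a single validated configuration object, a flat
# key=value config-file reader, and run_analysis() tying together reading,
# preprocessing, RSA, OSA, clinical parameters and the optional HRV path.

#' Build a validated run configuration
#'
#' Collects every tunable of the pipeline with its documented default:
#' band extraction 0.008-0.15 Hz Butterworth, artifact Method 1 at
#' threshold 4.2 (Method 2 default would be 1.6), RSA 240 s segments with
#' 120 s overlap and 4096 spectral samples, normogastria 2-4 cpm, OSA by
#' 4-minute averaged Tukey periodograms, slow-wave-coupling tolerance
#' 0.2 cpm, HRV windows 256 s with 128 s overlap.
#'
#' @param filter A [filter_spec()].
#' @param artifact_method 1 or 2.
#' @param artifact_threshold Multiplier; `NULL` picks the method default
#'   (4.2 / 1.6).
#' @param manual_intervals_min Optional list of `c(start, end)` minutes.
#' @param rsa An [rsa_config()].
#' @param osa_method `"periodogram4"`, `"ar4"` or `"ar1"`.
#' @param include_meal Include the meal period in OSA averaging.
#' @param swc_tol_cpm Slow-wave-coupling tolerance in cpm.
#' @param pic_scale `"linear"` or `"db"` power-instability scale.
#' @param hrv_enabled Run the HRV sub-pipeline (needs fs >= 100 Hz).
#' @param hrv_channel Channel for R-peak detection (default first).
#' @param hrv_window_s,hrv_overlap_s HRV spectral window geometry.
#' @param seed Seed applied before any stochastic step (none in the
#'   analysis path itself; kept for config completeness).
#' @return A `run_config` list.
#' @export
run_config <- function(filter = filter_spec(),
                       artifact_method = 1, artifact_threshold = NULL,
                       manual_intervals_min = NULL,
                       rsa = rsa_config(),
                       osa_method = "periodogram4", include_meal = FALSE,
                       swc_tol_cpm = 0.2, pic_scale = "linear",
                       hrv_enabled = FALSE, hrv_channel = NULL,
                       hrv_window_s = 256, hrv_overlap_s = 128,
                       seed = 1) {
  if (!artifact_method %in% c(1, 2)) stop_invalid("artifact method must be 1 or 2")
  if (is.null(artifact_threshold))
    artifact_threshold <- if (artifact_method == 1) 4.2 else 1.6
  if (artifact_threshold <= 0) stop_invalid("artifact threshold must be > 0")
  osa_method <- match.arg(osa_method, c("periodogram4", "ar4", "ar1"))
  structure(list(filter = filter, artifact_method = artifact_method,
                 artifact_threshold = artifact_threshold,
                 manual_intervals_min = manual_intervals_min, rsa = rsa,
                 osa_method = osa_method, include_meal = include_meal,
                 swc_tol_cpm = swc_tol_cpm, pic_scale = pic_scale,
                 hrv_enabled = hrv_enabled, hrv_channel = hrv_channel,
                 hrv_window_s = hrv_window_s, hrv_overlap_s = hrv_overlap_s,
                 seed = seed),
            class = "run_config")
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Recognized keys:
#' `filter.method`, `filter.low_hz`, `filter.high_hz`, `artifact.method`,
#' `artifact.threshold`, `artifact.manual_intervals` (semicolon-separated
#' `start-end` minute pairs), `rsa.lseg_s`, `rsa.sseg_s`, `rsa.lspv`,
#' `rsa.method`, `normo.low_cpm`, `normo.high_cpm`, `osa.method`,
#' `osa.include_meal`, `swc.tolerance_cpm`, `pic.scale`, `hrv.enabled`,
#' `hrv.channel`, `hrv.window_s`, `hrv.overlap_s`, `seed`.
#'
#' @param path Path to the config file.
#' @param base A `run_config` supplying defaults for unset keys.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, base = run_config()) {
  if (!file.exists(path)) stop_format("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  g <- function(key, default, as = identity)
    if (is.null(kv[[key]])) default else as(kv[[key]])
  num <- as.numeric
  lgl <- function(v) tolower(v) %in% c("true", "1", "yes")
  manual <- NULL
  if (!is.null(kv[["artifact.manual_intervals"]])) {
    manual <- lapply(strsplit(kv[["artifact.manual_intervals"]], ";")[[1]],
                     function(p) as.numeric(strsplit(trimws(p), "-")[[1]]))
  }
  run_config(
    filter = filter_spec(g("filter.method", base$filter$method),
                         g("filter.low_hz", base$filter$low_hz, num),
                         g("filter.high_hz", base$filter$high_hz, num)),
    artifact_method = g("artifact.method", base$artifact_method, num),
    artifact_threshold = g("artifact.threshold", NULL, num),
    manual_intervals_min = manual %||% base$manual_intervals_min,
    rsa = rsa_config(lseg_s = g("rsa.lseg_s", base$rsa$lseg_s, num),
                     sseg_s = g("rsa.sseg_s", base$rsa$sseg_s, num),
                     lspv = g("rsa.lspv", base$rsa$lspv, num),
                     normo_cpm = c(g("normo.low_cpm", base$rsa$normo_cpm[1], num),
                                   g("normo.high_cpm", base$rsa$normo_cpm[2], num)),
                     method = g("rsa.method", base$rsa$method)),
    osa_method = g("osa.method", base$osa_method),
    include_meal = g("osa.include_meal", base$include_meal, lgl),
    swc_tol_cpm = g("swc.tolerance_cpm", base$swc_tol_cpm, num),
    pic_scale = g("pic.scale", base$pic_scale),
    hrv_enabled = g("hrv.enabled", base$hrv_enabled, lgl),
    hrv_channel = g("hrv.channel", base$hrv_channel),
    hrv_window_s = g("hrv.window_s", base$hrv_window_s, num),
    hrv_overlap_s = g("hrv.overlap_s", base$hrv_overlap_s, num),
    seed = g("seed", base$seed, num))
}

#' Run the complete EGG analysis pipeline
#'
#' Reads (or accepts) a recording, optionally runs HRV on the raw
#' high-rate signal, downsamples to 4 Hz, extracts the slow-wave band,
#' flags artifacts (shared across channels), runs the RSA and OSA, and
#' derives the full clinical parameter set including per-channel fed/fast
#' power ratios. Progress is logged to `stderr` when `verbose`.
#'
#' @param input Path to an ASCII EGG file, or an [egg_recording()].
#' @param cfg A [run_config()].
#' @param verbose Log stage progress to stderr (default `FALSE`).
#' @return List of class `egg_analysis`: `source`, `config`, `plan`,
#'   `mask`, `rsa`, `osa`, `parameters` (with `fed_fast`), `hrv` (or
#'   `NULL`).
#' @export
run_analysis <- function(input, cfg = run_config(), verbose = FALSE) {
  log_stage <- function(...) if (verbose) message(sprintf(...))
  src <- if (is.character(input)) input else NULL
  log_stage("reading %s", src %||% "<in-memory recording>")
  rec <- if (is.character(input)) read_egg_ascii(input) else input
  stopifnot(inherits(rec, "egg_recording"))

  hrv <- NULL
  if (isTRUE(cfg$hrv_enabled)) {
    log_stage("HRV sub-pipeline (channel %s)", cfg$hrv_channel %||% rec$channels[1])
    hrv <- run_hrv(rec, channel = cfg$hrv_channel,
                   window_s = cfg$hrv_window_s, overlap_s = cfg$hrv_overlap_s)
  }

  log_stage("anti-alias downsampling %g Hz -> 4 Hz", rec$fs_hz)
  down <- antialias_downsample(rec)
  log_stage("band extraction %g-%g Hz (%s)", cfg$filter$low_hz,
            cfg$filter$high_hz, cfg$filter$method)
  egg <- extract_egg(down, cfg$filter)

  log_stage("artifact detection (method %d, threshold %g)",
            cfg$artifact_method, cfg$artifact_threshold)
  eggm <- egg_channel_matrix(egg)
  masks <- lapply(seq_len(ncol(eggm)), function(i)
    detect_artifacts(eggm[, i], egg$fs_hz, cfg$rsa$lseg_s,
                     cfg$artifact_method, cfg$artifact_threshold))
  mask <- combine_masks(masks, cfg$manual_intervals_min)

  plan <- build_period_plan(egg$meta, rec_duration_s(egg))
  log_stage("RSA (%s, %g s segments)", cfg$rsa$method, cfg$rsa$lseg_s)
  rsa <- run_rsa(egg, mask, cfg$rsa)
  log_stage("OSA (%s)", cfg$osa_method)
  osa <- run_osa(egg, mask, plan, cfg$osa_method, cfg$rsa$lspv,
                 cfg$rsa$normo_cpm, cfg$rsa$df_range_cpm, cfg$include_meal)
  log_stage("clinical parameters")
  params <- compute_egg_parameters(rsa, plan, cfg$swc_tol_cpm, cfg$pic_scale)
  params$fed_fast <- fed_fast_table(osa)

  structure(list(source = src, config = cfg, plan = plan, mask = mask,
                 rsa = rsa, osa = osa, parameters = params, hrv = hrv),
            class = "egg_analysis")
}

# internal: per-channel fed/fast power ratios (each postprandial period vs
# the pre-prandial one)
fed_fast_table <- function(osa) {
  rows <- list()
  for (ch in names(osa$channels)) {
    periods <- osa$channels[[ch]]$periods
    pre <- periods[["preprandial"]]
    if (is.null(pre)) next
    for (lbl in grep("^postprandial", names(periods), value = TRUE)) {
      ff <- fed_fast_power_ratio(pre$odp_db, periods[[lbl]]$odp_db)
      rows[[length(rows) + 1L]] <- data.frame(
        channel = ch, period = lbl, ratio = ff$ratio, diff_db = ff$diff_db,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' @export
print.egg_analysis <- function(x, ...) {
  cat(sprintf("<egg_analysis> %s\n", x$source %||% "<in-memory recording>"))
  cat(sprintf("  periods: %s\n", paste(x$plan$label, collapse = ", ")))
  cat(sprintf("  artifacts: %d/%d segments excluded\n", sum(x$mask$flags),
              length(x$mask$flags)))
  per <- x$parameters$periods
  wh <- per[per$period == "whole", , drop = FALSE]
  if (nrow(wh) == 0L) wh <- per
  for (i in seq_len(nrow(wh)))
    cat(sprintf("  %s [%s]: DF %.2f cpm, NI %.1f%%\n", wh$channel[i],
                wh$period[i], wh$df_mean_cpm[i], wh$pct_normo[i]))
  if (!is.null(x$hrv))
    cat(sprintf("  HRV: mean RR %.0f ms, RMSSD %.1f ms\n",
                x$hrv$time$mean_rr_ms, x$hrv$time$rmssd_ms))
  invisible(x)
}
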