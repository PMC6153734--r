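# Helpers to fabricate RSA segment rows with known values.
seg_rows <- function(df, dp = rep(-10, length(df)), channel = "A1",
                     excluded = rep(FALSE, length(df)),
                     rhythm = NULL) {
  if (is.null(rhythm))
    rhythm <- ifelse(is.na(df), "arrhythmia",
                     vapply(df, classify_rhythm, character(1)))
  data.frame(channel = channel, segment = seq_along(df),
             t_start_s = (seq_along(df) - 1) * 120, excluded = excluded,
             df_cpm = df, dp_db = dp, rhythm = rhythm,
             corrected = FALSE, stringsAsFactors = FALSE)
}

test_that("rhythm percentages count included segments and sum to 100", {
  s <- seg_rows(c(rep(3, 9), 1))
  pc <- rhythm_percentages(s)
  expect_equal(unname(pc["normo"]), 90)
  expect_equal(unname(pc["brady"]), 10)
  expect_equal(sum(pc), 100)

  all_arr <- seg_rows(rep(NA_real_, 5))
  expect_equal(unname(rhythm_percentages(all_arr)),
               c(0, 0, 0, 100))

  # excluded segments leave the denominator
  s2 <- seg_rows(c(3, 3, 5, NA), excluded = c(FALSE, FALSE, FALSE, TRUE))
  pc2 <- rhythm_percentages(s2)
  expect_equal(sum(pc2), 100)
  expect_equal(unname(pc2["tachy"]), 100 / 3, tolerance = 1e-9)

  set.seed(51)
  for (i in 1:5) {
    r <- seg_rows(sample(c(1, 3, 5, NA), 20, replace = TRUE))
    expect_equal(sum(rhythm_percentages(r)), 100)
  }
})

test_that("DF/DP statistics use non-arrhythmic included segments only", {
  s <- seg_rows(c(2.9, 3.0, 3.1))
  st <- df_dp_statistics(s)
  expect_equal(st$df_mean_cpm, 3)
  expect_equal(st$df_median_cpm, 3)

  one <- df_dp_statistics(seg_rows(3.2))
  expect_equal(one$df_sd_cpm, 0)

  dfs <- c(2.2, 3.7, 2.9, 3.1, 4.4)
  st5 <- df_dp_statistics(seg_rows(dfs))
  expect_equal(st5$df_mean_cpm, sum(dfs) / 5)
  expect_equal(st5$df_sd_cpm, sqrt(sum((dfs - mean(dfs))^2) / 4))

  with_arr <- seg_rows(c(3, NA, 3.2))
  expect_equal(df_dp_statistics(with_arr)$n_used, 2L)
})

test_that("instability coefficients are coefficients of variation", {
  expect_equal(instability_coefficients(seg_rows(rep(3, 6)))$fic, 0)

  s <- seg_rows(c(2, 4))
  ic <- instability_coefficients(s)
  expect_equal(ic$fic, sd(c(2, 4)) / mean(c(2, 4)))

  # scaling all linear powers x10 (+10 dB) leaves PIC unchanged
  s1 <- seg_rows(c(3, 3.2, 2.8), dp = c(-12, -9, -11))
  s2 <- seg_rows(c(3, 3.2, 2.8), dp = c(-2, 1, -1))
  expect_equal(instability_coefficients(s1)$pic,
               instability_coefficients(s2)$pic, tolerance = 1e-12)
  # ... but not when PIC is computed on the dB series
  expect_false(isTRUE(all.equal(
    instability_coefficients(s1, "db")$pic,
    instability_coefficients(s2, "db")$pic)))

  expect_true(is.na(instability_coefficients(seg_rows(3.0))$fic))
})

test_that("maximum DF difference is max minus min over usable segments", {
  expect_equal(max_df_difference(seg_rows(c(2.5, 3.0, 3.5))), 1)
  expect_equal(max_df_difference(seg_rows(3.1)), 0)
  set.seed(52)
  dfs <- runif(20, 0.5, 9)
  expect_equal(max_df_difference(seg_rows(dfs)), max(dfs) - min(dfs))
})

test_that("slow-wave coupling counts agreeing segment pairs and is symmetric", {
  a <- seg_rows(rep(3, 8), channel = "A1")
  expect_equal(slow_wave_coupling(a, seg_rows(rep(3, 8), channel = "A2")), 100)
  expect_equal(slow_wave_coupling(a, seg_rows(rep(3.5, 8), channel = "A2")), 0)

  set.seed(53)
  df_a <- runif(30, 2, 4)
  df_b <- df_a + rnorm(30, sd = 0.2)
  sa <- seg_rows(df_a, channel = "A1")
  sb <- seg_rows(df_b, channel = "A2")
  got <- slow_wave_coupling(sa, sb, tol_cpm = 0.2)
  expect_equal(got, mean(abs(df_a - df_b) <= 0.2) * 100)
  expect_identical(slow_wave_coupling(sa, sb), slow_wave_coupling(sb, sa))

  # pairs where either DF is missing are dropped from the denominator
  sa2 <- seg_rows(c(3, NA, 3, 3), channel = "A1")
  sb2 <- seg_rows(c(3, 3, NA, 3.5), channel = "A2")
  expect_equal(slow_wave_coupling(sa2, sb2), 50)
})

test_that("spatial DP difference spans the per-channel mean dominant powers", {
  four <- do.call(rbind, Map(function(ch, dp) seg_rows(rep(3, 4), dp = rep(dp, 4),
                                                       channel = ch),
                             c("A1", "A2", "A3", "A4"), c(30, 28, 25, 27)))
  expect_equal(spatial_dp_difference(four), 5)
  shuffled <- four[sample(nrow(four)), ]
  expect_equal(spatial_dp_difference(shuffled), 5)
  same <- do.call(rbind, lapply(c("A1", "A2"), function(ch)
    seg_rows(rep(3, 4), dp = rep(-10, 4), channel = ch)))
  expect_equal(spatial_dp_difference(same), 0)
  expect_true(is.na(spatial_dp_difference(seg_rows(rep(3, 4)))))
})

test_that("fed/fast power ratio follows the dB definition", {
  expect_equal(fed_fast_power_ratio(-10, -10)$ratio, 1)
  expect_equal(fed_fast_power_ratio(-20, -10)$ratio, 10)
  ab <- fed_fast_power_ratio(-13, -6)$ratio
  ba <- fed_fast_power_ratio(-6, -13)$ratio
  expect_equal(ab * ba, 1, tolerance = 1e-12)
  expect_true(is.na(fed_fast_power_ratio(NA, -10)$ratio))
})

test_that("the full parameter table on a clean record is perfect", {
  rec <- clean_rec_4hz(duration_min = 30)
  rsa <- run_rsa(extract_egg(rec))
  pars <- compute_egg_parameters(rsa)
  per <- pars$periods
  expect_true(all(per$pct_normo == 100))
  expect_true(all(per$fic < 0.05))
  expect_true(all(pars$swc$swc_pct == 100))
  expect_true(all(abs(per$pct_brady + per$pct_normo + per$pct_tachy +
                      per$pct_arrhythmia - 100) < 1e-6))
})
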