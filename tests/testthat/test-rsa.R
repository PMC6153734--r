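test_that("segmentation advances by lseg - sseg and drops partial tails", {
  x <- rep(0, 1800 * 4)
  segs <- segment_signal(x, 4, 240, 120)
  expect_length(segs, 14)     # floor((1800-240)/120) + 1
  expect_equal(sapply(segs, `[[`, "t_start_s"), seq(0, 1560, by = 120))
  expect_true(all(lengths(lapply(segs, `[[`, "samples")) == 960))

  disjoint <- segment_signal(x, 4, 180, 0)
  expect_equal(sapply(disjoint, `[[`, "t_start_s"), seq(0, 1620, by = 180))

  one <- segment_signal(rep(0, 240 * 4), 4, 240, 120)
  expect_length(one, 1)
  expect_error(segment_signal(rep(0, 100), 4, 240, 120),
               class = "eggwave_validation_error")
})

test_that("AR order equals the exhaustive AIC argmin plus 6", {
  set.seed(21)
  # a known AR(2) process: argmin should sit near the true order
  x <- as.numeric(stats::arima.sim(list(ar = c(0.75, -0.5)), 600))
  argmin <- ar_aic_argmin(x)
  expect_true(argmin %in% 2:4)
  expect_equal(select_ar_order(x), argmin + 6L)

  # white noise favours very low orders
  wn <- rnorm(600)
  expect_lte(ar_aic_argmin(wn), 3)
  expect_equal(select_ar_order(wn), ar_aic_argmin(wn) + 6L)

  # definitional identity on arbitrary inputs
  for (seed in 1:5) {
    set.seed(seed)
    y <- as.numeric(stats::arima.sim(list(ar = runif(1, -0.5, 0.9)), 400)) +
      sin(seq_len(400) / 7)
    expect_equal(select_ar_order(y), ar_aic_argmin(y) + 6L)
  }

  # degenerate constant segment falls back to 1 + 6
  expect_equal(select_ar_order(rep(2.5, 400)), 7L)
})

test_that("AR spectrum localizes a slow-wave peak and is nonnegative", {
  set.seed(22)
  t <- seq(0, 240 - 0.25, by = 0.25)
  x <- 0.15 * sin(2 * pi * 0.05 * t) + rnorm(length(t), sd = 0.02)
  spec <- psd_ar(x, 4)
  expect_true(all(spec$psd >= 0))
  expect_lt(abs(spec$freq_cpm[which.max(spec$psd)] - 3), 0.2)

  # white noise: no peak above 3x the in-band median (fixed seed)
  wn <- rnorm(960)
  sw <- psd_ar(wn, 4)
  inband <- sw$psd[sw$freq_cpm >= 0.5 & sw$freq_cpm <= 9]
  expect_lt(max(inband), 3 * stats::median(inband))
})

test_that("periodogram equals the brute-force DFT oracle for n <= 64", {
  set.seed(23)
  for (win in c("tukey", "barthann", "hann")) {
    for (n in c(16, 48, 64)) {
      x <- rnorm(n) + sin(seq_len(n))
      got <- psd_periodogram(x, 4, win, lspv = 64)
      expect_equal(got$psd, brute_dft_psd(x, 4, win, 64), tolerance = 1e-12,
                   label = sprintf("%s n=%d", win, n))
      expect_equal(got$freq_cpm, (0:63) * 4 / 128 * 60)
    }
  }
  expect_equal(max(psd_periodogram(rep(0, 32), 4, "hann", 64)$psd), 0)
})

test_that("periodogram peak of a 3 cpm sine lands within one grid step", {
  t <- seq(0, 240 - 0.25, by = 0.25)
  spec <- psd_periodogram(0.1 * sin(2 * pi * 0.05 * t), 4, "tukey", 4096)
  step <- diff(spec$freq_cpm[1:2])
  expect_lt(abs(spec$freq_cpm[which.max(spec$psd)] - 3), step + 1e-9)
})

test_that("the 2.5 dB rule corrects or rejects a DC-dominated spectrum", {
  direct <- find_dominant(two_peak_spectrum(gap_db = -10))  # side peak dominant
  expect_equal(direct$df_cpm, 3, tolerance = 0.06)
  expect_false(direct$corrected)

  corrected <- find_dominant(two_peak_spectrum(gap_db = 1))
  expect_false(corrected$arrhythmia)
  expect_true(corrected$corrected)
  expect_equal(corrected$df_cpm, 3, tolerance = 0.06)

  rejected <- find_dominant(two_peak_spectrum(gap_db = 4))
  expect_true(rejected$arrhythmia)
  expect_true(is.na(rejected$df_cpm))
  expect_true(is.na(rejected$dp_db))
})

test_that("whenever a DF is corrected the recomputed dB gap is below 2.5", {
  for (gap in seq(0.2, 5, by = 0.4)) {
    spec <- two_peak_spectrum(gap_db = gap)
    dom <- find_dominant(spec)
    if (dom$corrected) {
      recomputed <- power_db(max(spec$psd)) - dom$dp_db
      expect_lt(recomputed, 2.5)
    }
    if (!dom$arrhythmia)
      expect_true(dom$df_cpm >= 0.5 && dom$df_cpm <= 9)
  }
})

test_that("rhythm classes follow the normogastria band edges", {
  expect_equal(classify_rhythm(3.0), "normogastria")
  expect_equal(classify_rhythm(1.0), "bradygastria")
  expect_equal(classify_rhythm(5.0), "tachygastria")
  expect_equal(classify_rhythm(NA_real_), "arrhythmia")
  # band edges are inclusive for normogastria
  expect_equal(classify_rhythm(2.0), "normogastria")
  expect_equal(classify_rhythm(4.0), "normogastria")
  expect_equal(classify_rhythm(4.0001), "tachygastria")
})

test_that("run_rsa classifies a clean 3 cpm record as fully normogastric", {
  rec <- clean_rec_4hz(duration_min = 30)
  rsa <- run_rsa(extract_egg(rec))
  segs <- rsa$segments
  expect_equal(nrow(segs), 14 * 4)
  expect_true(all(segs$rhythm == "normogastria"))
  expect_true(all(abs(segs$df_cpm - 3) < 0.05))
})

test_that("a flagged artifact tile excludes the segment in every channel", {
  rec <- clean_rec_4hz(duration_min = 30)
  mask <- artifact_mask(c(rep(FALSE, 3), TRUE, rep(FALSE, 3)), 240)
  rsa <- run_rsa(extract_egg(rec), mask)
  segs <- rsa$segments
  # tile 4 covers [720, 960): overlapping analysis segments start at 480..960
  excl <- segs[segs$excluded, ]
  expect_setequal(unique(excl$channel), c("A1", "A2", "A3", "A4"))
  expect_true(all(table(excl$channel) == nrow(excl) / 4))
  expect_true(all(is.na(excl$df_cpm)))
  expect_true(all(excl$rhythm == "excluded"))
  kept <- segs[!segs$excluded, ]
  expect_true(all(kept$df_cpm >= 0.5 & kept$df_cpm <= 9))
})
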