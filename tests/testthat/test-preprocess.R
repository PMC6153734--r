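fs4 <- 4
t4 <- function(minutes) seq(0, minutes * 60 - 1 / fs4, by = 1 / fs4)

test_that("all filter modes pass an in-band sine with zero phase lag", {
  t <- t4(30)
  x <- sin(2 * pi * 0.05 * t)   # 3 cpm
  rec <- egg_recording(matrix(rep(x, 4), ncol = 4), fs4)
  for (m in c("butterworth", "zero_phase_inverse_butterworth", "ib_dct")) {
    y <- extract_egg(rec, filter_spec(m))$data[, 1]
    mid <- 2000:5000                       # away from the edges
    expect_lt(abs(max(abs(y[mid])) - 1), 0.01, label = paste(m, "amplitude"))
    cc <- stats::ccf(y[mid], x[mid], lag.max = 5, plot = FALSE)
    expect_lte(abs(cc$lag[which.max(cc$acf)]), 1, label = paste(m, "lag"))
  }
})

test_that("out-of-band components are strongly attenuated", {
  t <- t4(30)
  ecg_like <- sin(2 * pi * 1.2 * t)
  dc <- rep(1, length(t))
  for (m in c("butterworth", "zero_phase_inverse_butterworth", "ib_dct")) {
    rec <- egg_recording(cbind(A1 = ecg_like, A2 = dc), fs4,
                         channels = c("A1", "A2"))
    out <- extract_egg(rec, filter_spec(m))
    mid <- 2000:5000
    atten_db <- 20 * log10(max(abs(out$data[mid, 1])) / 1)
    expect_lt(atten_db, -40, label = paste(m, "@ 1.2 Hz"))
    expect_lt(max(abs(out$data[mid, 2])), 1e-3, label = paste(m, "DC"))
  }
})

test_that("the sensor channel passes through band extraction untouched", {
  t <- t4(10)
  sens <- sin(2 * pi * 0.5 * t)
  rec <- egg_recording(cbind(sin(2 * pi * 0.05 * t), sens), fs4,
                       channels = c("A1", "sensor"))
  out <- extract_egg(rec)
  expect_identical(out$data[, "sensor"], sens)
})

test_that("anti-alias downsampling yields 4 Hz with preserved peak location", {
  rec <- synth_egg_recording(freq_cpm = 3, snr_db = Inf, duration_min = 9,
                             fs_hz = 200, n_channels = 1, seed = 1)
  down <- antialias_downsample(rec)
  expect_equal(down$fs_hz, 4)
  expect_equal(nrow(down$data), 9 * 60 * 4)
  spec <- psd_periodogram(down$data[3:2158, 1], 4, "rect", lspv = 4096)
  step <- diff(spec$freq_cpm[1:2])
  expect_lt(abs(spec$freq_cpm[which.max(spec$psd)] - 3), step + 1e-9)

  # fs exactly 4 Hz is the identity branch
  rec4 <- clean_rec_4hz(duration_min = 5)
  expect_identical(antialias_downsample(rec4), rec4)

  # non-integer decimation factor (250 Hz) still lands on 4 Hz
  rec250 <- synth_egg_recording(freq_cpm = 3, snr_db = Inf, duration_min = 2,
                                fs_hz = 250, n_channels = 1, seed = 1)
  d250 <- antialias_downsample(rec250)
  expect_equal(d250$fs_hz, 4)
  expect_equal(nrow(d250$data), 2 * 60 * 4)
})

test_that("artifact Method 1 flags exactly the spike-bearing segment", {
  set.seed(101)
  fs <- 4; seg_s <- 60; n_seg <- 10
  x <- rnorm(n_seg * seg_s * fs)
  x[5 * seg_s * fs + 17] <- 100      # one 100-sigma spike in segment 6
  mask <- detect_artifacts(x, fs, seg_s, method = 1, threshold = 4.2)
  # independent limit computation
  sds <- sapply(1:n_seg, function(i) sd(x[((i - 1) * seg_s * fs + 1):(i * seg_s * fs)]))
  limit <- mean(sds) * 4.2
  expected <- sapply(1:n_seg, function(i)
    any(abs(x[((i - 1) * seg_s * fs + 1):(i * seg_s * fs)]) > limit))
  expect_identical(mask$flags, expected)
  expect_identical(which(mask$flags), 6L)
})

test_that("artifact Method 2 spares homogeneous-variance segments", {
  set.seed(102)
  fs <- 4; seg_s <- 60
  x <- rnorm(10 * seg_s * fs)
  mask <- detect_artifacts(x, fs, seg_s, method = 2, threshold = 1.6)
  expect_false(any(mask$flags))
  # a segment with 3x the SD trips the 1.6x limit
  x2 <- x
  idx <- (4 * seg_s * fs + 1):(5 * seg_s * fs)
  x2[idx] <- x2[idx] * 3
  mask2 <- detect_artifacts(x2, fs, seg_s, method = 2, threshold = 1.6)
  expect_identical(which(mask2$flags), 5L)
})

test_that("all-zero signals produce no artifact flags (strict comparison)", {
  mask <- detect_artifacts(rep(0, 4 * 240 * 3), 4, 240, method = 1)
  expect_false(any(mask$flags))
  mask2 <- detect_artifacts(rep(0, 4 * 240 * 3), 4, 240, method = 2)
  expect_false(any(mask2$flags))
})

test_that("raising the threshold never flags a previously clean segment", {
  set.seed(103)
  for (method in 1:2) {
    x <- rnorm(4 * 60 * 12) * rep(c(1, 1, 4, 1, 1, 2, 1, 8, 1, 1, 1, 3),
                                  each = 4 * 60)
    prev <- NULL
    for (thr in c(0.5, 1, 1.6, 2.5, 4.2, 8)) {
      flags <- detect_artifacts(x, 4, 60, method, thr)$flags
      if (!is.null(prev)) expect_true(all(flags <= prev),
                                      label = sprintf("method %d thr %g", method, thr))
      prev <- flags
    }
  }
})

test_that("mask combination ORs channels and maps manual minutes to tiles", {
  m1 <- artifact_mask(c(F, F, F, F, T, F), 240, 1, 4.2)
  m2 <- artifact_mask(rep(FALSE, 6), 240, 1, 4.2)
  comb <- combine_masks(list(m1, m2, m2, m2))
  expect_identical(which(comb$flags), 5L)

  # 10-12 min exclusion on a 240 s grid covers tiles [480,720) and [720,960)
  comb2 <- combine_masks(n_segments = 6, segment_len_s = 240,
                         manual_intervals_min = list(c(10, 12)))
  expect_identical(which(comb2$flags), c(3L, 4L))

  expect_warning(
    comb3 <- combine_masks(n_segments = 4, segment_len_s = 240,
                           manual_intervals_min = list(c(14, 20))),
    "clipped")
  expect_identical(which(comb3$flags), 4L)

  empty <- combine_masks(n_segments = 5, segment_len_s = 240)
  expect_false(any(empty$flags))
  expect_error(combine_masks(list(m1, artifact_mask(rep(FALSE, 3), 240))),
               class = "eggwave_validation_error")
})

test_that("a clean synthetic record stays almost entirely unflagged", {
  rec <- synth_egg_recording(freq_cpm = 3, snr_db = 6, duration_min = 60,
                             fs_hz = 4, seed = 9)
  egg <- extract_egg(rec)
  for (method in 1:2) {
    masks <- lapply(1:4, function(i)
      detect_artifacts(egg$data[, i], 4, 240, method))
    comb <- combine_masks(masks)
    expect_gte(mean(!comb$flags), 0.95)
  }
})
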