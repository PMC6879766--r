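test_that("coverage needs half the window and 5 s of the central epoch", {
  # 140 s of valid IBIs in a 300-s window: below half
  ib <- constant_ibis(140)
  expect_false(epoch_coverage_ok(ib, 0, 300, epoch_start = 135))
  # full coverage passes
  expect_true(epoch_coverage_ok(constant_ibis(300), 0, 300, epoch_start = 135))
  # 200 s of coverage but only 4 s inside the central epoch
  ib <- constant_ibis(200)
  ib2 <- ib
  ib2$onset_s <- ib2$onset_s + ifelse(ib2$onset_s >= 131, 100, 0) # hole at the centre
  # valid intervals cover [0,131) and [231,300): central epoch [135,165) gets 0 s
  expect_false(epoch_coverage_ok(ib2, 0, 300, epoch_start = 135))
  # exactly 5 s in the centre is enough if the half-window rule also holds
  ib3 <- constant_ibis(160)
  expect_true(epoch_coverage_ok(ib3, 0, 300, epoch_start = 135))
  expect_false(epoch_coverage_ok(ib3, 0, 300,
    epoch_start = 135,
    nominal_length = 330
  ))
})

test_that("time-domain features are exact on a constant series", {
  ib <- constant_ibis(300, ibi = 0.8)
  fm <- extract_feature_matrix(ib, 10, families = "hrv_time")
  mid <- 5 # central epoch, fully covered window
  expect_equal(fm$mean_nn[mid], 800)
  expect_equal(fm$sdnn[mid], 0)
  expect_equal(fm$rmssd[mid], 0)
  expect_equal(fm$pnn50[mid], 0)
  expect_equal(fm$mean_hr[mid], 75)
  # undefined shape statistics on a degenerate series are missing
  expect_true(is.na(fm$skew_nn[mid]))
})

test_that("spectral features localise a known modulation frequency", {
  # IBIs modulated at 0.25 Hz -> HF power must dominate LF
  t <- 0
  onsets <- numeric(0)
  values <- numeric(0)
  while (t < 600) {
    ibi <- 1.0 + 0.05 * sin(2 * pi * 0.25 * t)
    onsets <- c(onsets, t)
    values <- c(values, ibi)
    t <- t + ibi
  }
  ib <- tibble::tibble(onset_s = onsets, ibi_s = values, valid = TRUE, reason = "ok")
  fm <- extract_feature_matrix(ib, 20, families = "hrv_freq")
  mid <- 10
  expect_gt(fm$hf_power[mid], 10 * fm$lf_power[mid])
  expect_equal(fm$hf_peak_freq[mid], 0.25, tolerance = 0.05)
  # and the converse for a 0.09 Hz modulation
  t <- 0
  onsets <- values <- numeric(0)
  while (t < 600) {
    ibi <- 1.0 + 0.05 * sin(2 * pi * 0.09 * t)
    onsets <- c(onsets, t)
    values <- c(values, ibi)
    t <- t + ibi
  }
  ib <- tibble::tibble(onset_s = onsets, ibi_s = values, valid = TRUE, reason = "ok")
  fm <- extract_feature_matrix(ib, 20, families = "hrv_freq")
  expect_gt(fm$lf_power[mid], 10 * fm$hf_power[mid])
})

test_that("DFA scaling of white noise is near one half", {
  set.seed(40)
  alphas <- replicate(8, {
    x <- rnorm(800, 1, 0.05)
    dfa_alpha(x, unique(round(2^seq(2, 6, by = 0.25))))
  })
  expect_lt(abs(mean(alphas) - 0.5), 0.05)
})

test_that("sample entropy matches a brute-force template count", {
  set.seed(41)
  x <- rnorm(60)
  r <- 0.2 * pop_sd(x)
  m <- 2
  brute <- function(mm) {
    cnt <- 0L
    for (i in 1:(60 - mm)) {
      for (j in 1:(60 - mm)) {
        if (i < j && max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) < r) {
          cnt <- cnt + 1L
        }
      }
    }
    cnt
  }
  expect_equal(sample_entropy(x, m, r), -log(brute(3) / brute(2)))
  expect_true(is.na(sample_entropy(rep(1, 100))))
})

test_that("the feature matrix honours registry, edges and shifts", {
  rec <- generate_recording(sim_config(duration_h = 1 / 6, target_ahi = 0, seed = 42))
  ib <- reject_invalid_ibis(
    tibble::tibble(
      onset_s = rec$ibis$onset_s, ibi_s = rec$ibis$ibi_s,
      valid = TRUE, reason = "ok"
    )
  )
  fm <- extract_feature_matrix(ib, 20, families = c("hrv_time", "multiscale_entropy"))
  reg <- feature_registry(c("hrv_time", "multiscale_entropy"))
  expect_setequal(setdiff(names(fm), c("record_id", "epoch")), reg$name)
  # all values finite or missing
  vals <- as.matrix(fm[, reg$name])
  expect_true(all(is.na(vals) | is.finite(vals)))
  # a recording whose beats start late fails coverage at the head only
  ib_late <- ib[ib$onset_s >= 150, ]
  fm_late <- extract_feature_matrix(ib_late, 20, families = "hrv_time")
  expect_true(is.na(fm_late$sdnn[1])) # window [0,165], covered 15 s < 150
  expect_false(is.na(fm_late$sdnn[10]))

  # shifting all onsets by one epoch shifts rows by one epoch
  ib2 <- ib
  ib2$onset_s <- ib2$onset_s + 30
  fm1 <- extract_feature_matrix(ib, 20, families = "hrv_time")
  fm2 <- extract_feature_matrix(ib2, 20, families = "hrv_time")
  inner <- 6:14 # away from both edges
  expect_equal(fm2$sdnn[inner + 1], fm1$sdnn[inner], tolerance = 1e-10)
})

test_that("event clusters elevate short-term IBI variability", {
  rec <- generate_recording(sim_config(duration_h = 1, target_ahi = 40, seed = 43))
  prep <- prepare_recording(rec, families = "hrv_time")
  re <- prep$sdnn[prep$re_class]
  quiet <- prep$sdnn[!prep$re_class]
  expect_gt(mean(re, na.rm = TRUE), mean(quiet, na.rm = TRUE))
})

test_that("activity counts respond to broadband movement amplitude", {
  rec <- generate_recording(sim_config(duration_h = 1 / 6, target_ahi = 0, seed = 44))
  ecg <- render_ecg(rec, sampling_rate = 128, noise_sd = 0.01)
  # inject a strong broadband burst in epoch 10
  idx <- (9 * 30 * 128):(10 * 30 * 128)
  ecg$samples[idx] <- ecg$samples[idx] + rnorm(length(idx), 0, 0.8)
  ib <- reject_invalid_ibis(
    tibble::tibble(
      onset_s = rec$ibis$onset_s, ibi_s = rec$ibis$ibi_s,
      valid = TRUE, reason = "ok"
    )
  )
  fm <- extract_feature_matrix(ib, 20, families = "activity_counts", ecg = ecg)
  expect_equal(which.max(fm$activity_counts), 10)
})

test_that("plugin families join the registry and the matrix", {
  register_feature_family("toy_range", 60, function(v, o, ctx) {
    c(toy_range = max(v) - min(v))
  })
  reg <- feature_registry(c("hrv_time", "toy_range"))
  expect_true("toy_range" %in% reg$name)
  ib <- constant_ibis(300)
  fm <- extract_feature_matrix(ib, 10, families = "toy_range")
  expect_true("toy_range" %in% names(fm))
  expect_equal(fm$toy_range[5], 0)
})
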