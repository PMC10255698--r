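test_that("temperature thresholding follows the 100.4 F fever rule", {
  expect_equal(classify_temperature(101.2), "fever")
  expect_equal(classify_temperature(98.6), "non-fever")
  expect_equal(classify_temperature(100.4), "fever")  # boundary: >= is fever
  expect_warning(out <- classify_temperature(150), "invalid|plausible")
  expect_equal(out, "invalid")
})

test_that("heart rate is classified against the age-appropriate band", {
  expect_equal(classify_heart_rate(200, 0, 0), "high")   # newborn 70-190
  expect_equal(classify_heart_rate(100, 0, 0), "normal")
  expect_equal(classify_heart_rate(72, 30), "normal")    # adult 60-100
  expect_equal(classify_heart_rate(55, 30), "low")
  expect_equal(classify_heart_rate(105, 30), "high")
  expect_equal(classify_heart_rate(100, 30), "normal")   # inclusive bound
  expect_equal(classify_heart_rate(150, 0, 6), "normal") # infant 80-160
})

test_that("an age with no configured band raises an explicit error", {
  partial <- list(hr_band(0, 12, 70, 190))
  expect_error(classify_heart_rate(80, 5, 0, table = partial),
               class = "ecgtriage_unresolved_band")
  # overlapping bands are equally unresolvable
  overlap <- list(hr_band(0, 24, 70, 190), hr_band(12, 36, 80, 130))
  expect_error(classify_heart_rate(80, 1, 6, table = overlap),
               class = "ecgtriage_unresolved_band")
})

test_that("SpO2 partitions into low / normal / invalid", {
  expect_equal(classify_spo2(97), "normal")
  expect_equal(classify_spo2(95), "normal")
  expect_equal(classify_spo2(92), "low")
  expect_warning(out <- classify_spo2(104), "104")
  expect_equal(out, "invalid")
})

test_that("vital classifications are monotone", {
  # raising temperature never turns fever into non-fever
  temps <- seq(95, 104, by = 0.1)
  flags <- vapply(temps, classify_temperature, character(1))
  fever_idx <- which(flags == "fever")
  expect_true(all(diff(fever_idx) == 1))  # contiguous upper range
  expect_true(all(flags[temps >= 100.4] == "fever"))
  # lowering SpO2 never turns low into normal
  sats <- seq(100, 80, by = -0.5)
  sflags <- vapply(sats, classify_spo2, character(1))
  low_start <- match("low", sflags)
  expect_true(all(sflags[low_start:length(sflags)] == "low"))
})

test_that("triage aggregates vitals and beat histogram into one decision", {
  quiet <- vitals_profile(jitter_sd = c(temp_f = 0, hr_bpm = 0, spo2_pct = 0))
  normal <- generate_vitals_stream(quiet, 10, seed = 1)
  rep0 <- triage(normal, beat_labels = rep(0L, 20))
  expect_false(rep0$alarm)
  expect_length(rep0$reasons, 0L)
  expect_equal(rep0$beat_class_histogram, c(20L, 0L, 0L, 0L, 0L))

  fever <- normal
  fever$temp_f[3] <- 101.0
  rep1 <- triage(fever, beat_labels = rep(0L, 20))
  expect_true(rep1$alarm)
  expect_true(any(grepl("fever", rep1$reasons)))

  # 30% PVC beats with normal vitals trips the abnormal-beat rule
  beats <- c(rep(0L, 14), rep(2L, 6))
  rep2 <- triage(normal, beat_labels = beats)
  expect_true(rep2$alarm)
  expect_true(any(grepl("abnormal beat fraction", rep2$reasons)))
  expect_equal(rep2$abnormal_beat_fraction, 0.3)
})

test_that("alarm is monotone: adding an abnormal sample never clears it", {
  quiet <- vitals_profile(jitter_sd = c(temp_f = 0, hr_bpm = 0, spo2_pct = 0))
  s <- generate_vitals_stream(quiet, 5, seed = 1)
  s$spo2_pct[2] <- 90
  base <- triage(s, beat_labels = rep(0L, 10))
  expect_true(base$alarm)
  worse <- rbind(s, s[1, ])
  worse$temp_f[6] <- 102
  rep_w <- triage(worse, beat_labels = rep(0L, 10))
  expect_true(rep_w$alarm)
  expect_gte(length(rep_w$reasons), length(base$reasons))
})

test_that("triage demands at least one input and reports reasons iff alarmed", {
  expect_error(triage(NULL, integer()), "at least one")
  ok <- triage(NULL, beat_labels = rep(0L, 5))
  expect_identical(ok$alarm, length(ok$reasons) > 0L)
  bad <- triage(NULL, beat_labels = rep(3L, 5))
  expect_identical(bad$alarm, length(bad$reasons) > 0L)
  expect_true(bad$alarm)
})
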