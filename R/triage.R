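# Rule-based vitals triage: fever thresholding, age-banded heart-rate
# classification, SpO2 range check, and the aggregate report-and-alarm
# decision.

#' Classify body temperature as fever or non-fever
#'
#' Fixed clinical threshold of 100.4 degrees F; readings at or above it are
#' fever (the >= convention matches the clinical definition the threshold
#' comes from). Values outside the plausible 80-115 F range flag as
#' "invalid" with a warning rather than classifying silently.
#'
#' @param temp_f Temperature in degrees Fahrenheit.
#' @param threshold_f Fever threshold (default 100.4).
#' @return One of "fever", "non-fever", "invalid".
#' @export
classify_temperature <- function(temp_f, threshold_f = 100.4) {
  check_scalar_number(temp_f, "temp_f")
  if (temp_f < 80 || temp_f > 115) {
    warning(sprintf("temperature %g F outside plausible range [80, 115]; flagged invalid",
                    temp_f))
    return("invalid")
  }
  if (temp_f >= threshold_f) "fever" else "non-fever"
}

#' One heart-rate reference band
#'
#' @param age_low_months,age_high_months Age range in months,
#'   half-open `[low, high)`.
#' @param hr_low,hr_high Inclusive normal heart-rate bounds in bpm.
#' @param source Provenance tag: "reference" for published pediatric/adult
#'   ranges, "default-extrapolated" for package-filled gaps, "user".
#' @return An object of class `hr_band`.
#' @export
hr_band <- function(age_low_months, age_high_months, hr_low, hr_high,
                    source = "user") {
  if (hr_low >= hr_high) abort_invalid("hr_low must be < hr_high")
  if (age_low_months >= age_high_months) {
    abort_invalid("age_low_months must be < age_high_months")
  }
  structure(list(age_low_months = age_low_months,
                 age_high_months = age_high_months,
                 hr_low = hr_low, hr_high = hr_high, source = source),
            class = "hr_band")
}

#' Default heart-rate band table
#'
#' Reference ranges: newborns 0-1 month 70-190 bpm, infants 1-11 months
#' 80-160 bpm, and ages 10 and up (adults and seniors) 60-100 bpm. The
#' child bands in between (1-2 y: 80-130; 3-5 y: 80-120; 6-9 y: 70-110)
#' are package defaults tagged "default-extrapolated" — they fill a gap in
#' the reference ranges and may be overridden with a user table.
#'
#' @return List of [hr_band()]s covering all ages without overlap.
#' @export
default_hr_bands <- function() {
  list(
    hr_band(0, 1, 70, 190, source = "reference"),
    hr_band(1, 12, 80, 160, source = "reference"),
    hr_band(12, 36, 80, 130, source = "default-extrapolated"),
    hr_band(36, 72, 80, 120, source = "default-extrapolated"),
    hr_band(72, 120, 70, 110, source = "default-extrapolated"),
    hr_band(120, Inf, 60, 100, source = "reference")
  )
}

#' Classify heart rate against the age-appropriate band
#'
#' @param hr_bpm Heart rate in beats per minute (> 0).
#' @param age_years,age_months Patient age (months in 0..11 on top of
#'   whole years).
#' @param table Band table, default [default_hr_bands()].
#' @return One of "low", "normal" (inclusive bounds), "high".
#' @export
classify_heart_rate <- function(hr_bpm, age_years, age_months = 0L,
                                table = default_hr_bands()) {
  check_scalar_number(hr_bpm, "hr_bpm")
  if (hr_bpm <= 0) abort_invalid("`hr_bpm` must be > 0")
  check_count(age_years, "age_years", lower = 0L)
  check_count(age_months, "age_months", lower = 0L)
  total_months <- age_years * 12L + age_months
  hits <- Filter(function(b) total_months >= b$age_low_months &&
                   total_months < b$age_high_months, table)
  if (length(hits) != 1L) {
    abort_invalid(sprintf(
      "age %d years %d months resolves to %d heart-rate bands; a band table must cover each age exactly once",
      age_years, age_months, length(hits)),
      class = "ecgtriage_unresolved_band")
  }
  b <- hits[[1L]]
  if (hr_bpm < b$hr_low) "low" else if (hr_bpm > b$hr_high) "high" else "normal"
}

#' Classify oxygen saturation
#'
#' Normal saturation is 95-100 percent; below 95 is low. Values outside
#' `[0, 100]` are physically impossible for percent saturation and flag as
#' sensor error ("invalid").
#'
#' @param spo2_pct SpO2 in percent.
#' @return One of "low", "normal", "invalid".
#' @export
classify_spo2 <- function(spo2_pct) {
  check_scalar_number(spo2_pct, "spo2_pct")
  if (spo2_pct < 0 || spo2_pct > 100) {
    warning(sprintf("SpO2 reading %g%% outside [0, 100]; flagged invalid (sensor error)",
                    spo2_pct))
    return("invalid")
  }
  if (spo2_pct >= 95) "normal" else "low"
}

#' Alarm policy for the triage decision
#'
#' @param abnormal_beat_fraction Alarm when the fraction of non-class-0
#'   beats exceeds this (default 0.2).
#' @param fever_threshold_f Fever threshold forwarded to
#'   [classify_temperature()].
#' @param hr_bands Heart-rate band table.
#' @return An object of class `triage_policy`.
#' @export
triage_policy <- function(abnormal_beat_fraction = 0.2,
                          fever_threshold_f = 100.4,
                          hr_bands = default_hr_bands()) {
  check_scalar_number(abnormal_beat_fraction, "abnormal_beat_fraction", 0, 1)
  structure(list(abnormal_beat_fraction = abnormal_beat_fraction,
                 fever_threshold_f = fever_threshold_f,
                 hr_bands = hr_bands),
            class = "triage_policy")
}

#' Triage a monitoring window
#'
#' Classifies every vitals reading (temperature, age-banded heart rate,
#' SpO2), tallies the beat-class histogram, and takes the report-and-alarm
#' decision: alarm if and only if any reading shows fever, low/high heart
#' rate, or low SpO2, or the fraction of non-normal (non-class-0) beats
#' exceeds the policy threshold. Every triggered condition is listed in
#' `reasons`, so `alarm == (length(reasons) > 0)`.
#'
#' @param samples Vitals data.frame as produced by
#'   [generate_vitals_stream()] (columns `timestamp`, `temp_f`, `hr_bpm`,
#'   `spo2_pct`, `age_years`, `age_months`); may have zero rows if beat
#'   labels are supplied.
#' @param beat_labels Integer vector of predicted beat classes 0..4 (may be
#'   empty if vitals are supplied).
#' @param policy A [triage_policy()].
#' @return A `triage_report`: list with `flags` (per-reading data.frame of
#'   temperature/heart-rate/SpO2 categories), `beat_class_histogram`
#'   (named counts over "0".."4"), `abnormal_beat_fraction`, `alarm`, and
#'   `reasons` (character).
#' @export
triage <- function(samples = NULL, beat_labels = integer(),
                   policy = triage_policy()) {
  n_vitals <- if (is.null(samples)) 0L else nrow(samples)
  if (n_vitals == 0L && length(beat_labels) == 0L) {
    abort_invalid("triage needs at least one vitals sample or one beat label")
  }
  reasons <- character()
  flags <- NULL
  if (n_vitals > 0L) {
    temp_flag <- character(n_vitals)
    hr_flag <- character(n_vitals)
    spo2_flag <- character(n_vitals)
    for (i in seq_len(n_vitals)) {
      temp_flag[i] <- classify_temperature(samples$temp_f[i],
                                           policy$fever_threshold_f)
      hr_flag[i] <- classify_heart_rate(samples$hr_bpm[i],
                                        samples$age_years[i],
                                        samples$age_months[i],
                                        policy$hr_bands)
      spo2_flag[i] <- classify_spo2(samples$spo2_pct[i])
    }
    flags <- data.frame(timestamp = samples$timestamp,
                        temperature = temp_flag,
                        heart_rate = hr_flag,
                        spo2 = spo2_flag)
    if (any(temp_flag == "fever")) {
      i <- which(temp_flag == "fever")
      reasons <- c(reasons, sprintf(
        "fever: %d reading(s) at or above %.1f F (max %.1f F)",
        length(i), policy$fever_threshold_f, max(samples$temp_f[i])))
    }
    for (dir in c("low", "high")) {
      if (any(hr_flag == dir)) {
        i <- which(hr_flag == dir)
        reasons <- c(reasons, sprintf(
          "heart rate %s for age: %d reading(s) (extreme %.0f bpm)",
          dir, length(i),
          if (dir == "low") min(samples$hr_bpm[i]) else max(samples$hr_bpm[i])))
      }
    }
    if (any(spo2_flag == "low")) {
      i <- which(spo2_flag == "low")
      reasons <- c(reasons, sprintf(
        "low SpO2: %d reading(s) below 95%% (min %.1f%%)",
        length(i), min(samples$spo2_pct[i])))
    }
    if (any(temp_flag == "invalid") || any(spo2_flag == "invalid")) {
      reasons <- c(reasons, "invalid sensor reading(s) present")
    }
  }
  hist <- table(factor(beat_labels, levels = 0:4))
  abn_frac <- if (length(beat_labels)) {
    mean(beat_labels != 0L)
  } else {
    0
  }
  if (length(beat_labels) && abn_frac > policy$abnormal_beat_fraction) {
    reasons <- c(reasons, sprintf(
      "abnormal beat fraction %.2f exceeds threshold %.2f",
      abn_frac, policy$abnormal_beat_fraction))
  }
  structure(
    list(flags = flags,
         beat_class_histogram = as.integer(hist),
         abnormal_beat_fraction = abn_frac,
         alarm = length(reasons) > 0L,
         reasons = reasons),
    class = "triage_report"
  )
}

#' @export
print.triage_report <- function(x, ...) {
  cat(sprintf("Triage: %s\n", if (x$alarm) "ALARM" else "all within normal limits"))
  if (length(x$reasons)) cat(paste0("  - ", x$reasons, collapse = "\n"), "\n")
  cat("beat class histogram (0..4):",
      paste(x$beat_class_histogram, collapse = " "), "\n")
  invisible(x)
}
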