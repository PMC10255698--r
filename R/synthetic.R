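# Synthetic ECG beats and vitals streams.
#
# A beat is modelled as a sum of Gaussian bumps (the canonical P, Q, R, S, T
# deflections) on a flat baseline, with optional per-wave timing jitter,
# additive white noise and low-frequency sinusoidal baseline wander. This is
# the standard phantom-ECG construction: analytically checkable, not a
# physiological simulation.

#' Class names for the five-class heartbeat scheme
#'
#' Label encoding used throughout the package: 0 = normal beat,
#' 1 = supraventricular premature beat, 2 = premature ventricular
#' contraction, 3 = fusion of ventricular and normal, 4 = unclassifiable.
#'
#' @return Character vector of length 5, named by the integer labels "0".."4".
#' @export
beat_class_names <- function() {
  c("0" = "Normal beat",
    "1" = "Supraventricular premature beat",
    "2" = "Premature ventricular contraction",
    "3" = "Fusion of ventricular",
    "4" = "Unclassifiable beat")
}

#' Construct a beat morphology
#'
#' A morphology is a set of Gaussian components (center, amplitude, width —
#' all expressed as fractions of the beat window, amplitudes in arbitrary
#' units) plus jitter/noise/wander parameters. The canonical five components
#' are named `P`, `Q`, `R`, `S`, `T`; composite morphologies (e.g. fusion
#' beats, which superpose two activation fronts) may carry more.
#'
#' @param class_label Integer class label in 0..4.
#' @param wave_centers Named numeric vector of component centers (fraction of
#'   beat, in (0, 1)).
#' @param wave_amplitudes Signed amplitudes, same length/names as centers.
#' @param wave_widths Positive Gaussian standard deviations (fraction of
#'   beat), same length as centers.
#' @param jitter_sd Standard deviation of independent per-wave center jitter
#'   (fraction of beat), >= 0.
#' @param noise_sd Standard deviation of additive white noise (amplitude
#'   units), >= 0.
#' @param wander_amp Amplitude of sinusoidal baseline wander (0 disables).
#' @param wander_cycles Baseline-wander cycles per beat window.
#' @return An object of class `beat_morphology`.
#' @export
beat_morphology <- function(class_label, wave_centers, wave_amplitudes,
                            wave_widths, jitter_sd = 0, noise_sd = 0,
                            wander_amp = 0, wander_cycles = 0.8) {
  check_count(class_label, "class_label", lower = 0L)
  if (class_label > 4L) abort_invalid("`class_label` must be in 0..4")
  n <- length(wave_centers)
  if (n < 1L || length(wave_amplitudes) != n || length(wave_widths) != n) {
    abort_invalid("wave_centers, wave_amplitudes, wave_widths must have equal length >= 1")
  }
  if (any(wave_widths <= 0)) abort_invalid("wave_widths must all be > 0")
  check_scalar_number(jitter_sd, "jitter_sd", lower = 0)
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  structure(
    list(class_label = as.integer(class_label),
         wave_centers = wave_centers,
         wave_amplitudes = wave_amplitudes,
         wave_widths = wave_widths,
         jitter_sd = jitter_sd,
         noise_sd = noise_sd,
         wander_amp = wander_amp,
         wander_cycles = wander_cycles),
    class = "beat_morphology"
  )
}

#' Default morphologies for the five beat classes
#'
#' Package constants chosen to make the classes morphologically separable;
#' they are synthetic conventions, not physiological claims:
#' * class 0 — textbook P-QRS-T with upright narrow R;
#' * class 1 — attenuated/absent P wave and early timing (all deflections
#'   shifted earlier in the window);
#' * class 2 — no P wave, widened inverted-polarity QRS with discordant T;
#' * class 3 — superposition of the class-0 and class-2 waveforms at half
#'   amplitude (a fusion beat blends both activation fronts);
#' * class 4 — a single broad low bump with high noise and timing jitter.
#'
#' @param noise_sd Baseline white-noise level for classes 0-3 (class 4 uses
#'   a much larger fixed value).
#' @return Named list of five [beat_morphology()] objects ("0".."4").
#' @export
default_morphologies <- function(noise_sd = 0.04) {
  centers0 <- c(P = 0.28, Q = 0.44, R = 0.50, S = 0.56, T = 0.72)
  amps0    <- c(P = 0.15, Q = -0.12, R = 1.00, S = -0.25, T = 0.30)
  widths0  <- c(P = 0.035, Q = 0.012, R = 0.018, S = 0.014, T = 0.060)

  m0 <- beat_morphology(0L, centers0, amps0, widths0,
                        jitter_sd = 0.008, noise_sd = noise_sd,
                        wander_amp = 0.05)

  # SVEB: P wave effectively absent, beat early in the window.
  m1 <- beat_morphology(1L, centers0 - 0.07,
                        c(P = 0.02, Q = -0.12, R = 0.95, S = -0.25, T = 0.28),
                        widths0,
                        jitter_sd = 0.008, noise_sd = noise_sd,
                        wander_amp = 0.05)

  # PVC: wide, inverted QRS, no P, discordant T.
  centers2 <- c(P = 0.28, Q = 0.42, R = 0.50, S = 0.58, T = 0.74)
  amps2    <- c(P = 0.00, Q = 0.20, R = -0.95, S = 0.30, T = -0.30)
  widths2  <- c(P = 0.035, Q = 0.030, R = 0.055, S = 0.030, T = 0.070)
  m2 <- beat_morphology(2L, centers2, amps2, widths2,
                        jitter_sd = 0.008, noise_sd = noise_sd,
                        wander_amp = 0.05)

  # Fusion: literal waveform average of classes 0 and 2.
  m3 <- beat_morphology(3L,
                        c(centers0, centers2),
                        c(amps0, amps2) / 2,
                        c(widths0, widths2),
                        jitter_sd = 0.008, noise_sd = noise_sd,
                        wander_amp = 0.05)

  # Unclassifiable: little structure, heavy noise and jitter.
  m4 <- beat_morphology(4L, c(R = 0.50), c(R = 0.20), c(R = 0.20),
                        jitter_sd = 0.05, noise_sd = 0.30,
                        wander_amp = 0.05)

  list("0" = m0, "1" = m1, "2" = m2, "3" = m3, "4" = m4)
}

#' Generate one synthetic ECG beat
#'
#' Evaluates the morphology's Gaussian mixture on `length` samples spanning
#' one beat window, adds jitter, white noise and baseline wander. The
#' function is a pure function of `(morph, length, seed)`.
#'
#' @param morph A [beat_morphology()].
#' @param length Number of samples (>= 32).
#' @param seed Integer seed controlling all randomness of this call.
#' @param fs Nominal sampling rate in Hz attached to the output (default 125).
#' @return A `beat_segment`: list with `samples` (numeric of `length`),
#'   `fs`, and `label` (the morphology's class label).
#' @export
generate_beat <- function(morph, length, seed = 0L, fs = 125) {
  if (!inherits(morph, "beat_morphology")) {
    abort_invalid("`morph` must be a beat_morphology object")
  }
  check_count(length, "length", lower = 1L)
  if (length < 32L) abort_invalid("`length` must be >= 32 samples")
  with_local_seed(seed, {
    tt <- (seq_len(length) - 0.5) / length
    nw <- base::length(morph$wave_centers)
    centers <- morph$wave_centers + rnorm(nw, 0, morph$jitter_sd)
    y <- numeric(length)
    for (w in seq_len(nw)) {
      y <- y + morph$wave_amplitudes[w] *
        exp(-0.5 * ((tt - centers[w]) / morph$wave_widths[w])^2)
    }
    if (morph$wander_amp > 0) {
      phase <- runif(1, 0, 2 * pi)
      y <- y + morph$wander_amp * sin(2 * pi * morph$wander_cycles * tt + phase)
    }
    if (morph$noise_sd > 0) y <- y + rnorm(length, 0, morph$noise_sd)
    structure(list(samples = as.numeric(y), fs = fs,
                   label = morph$class_label),
              class = "beat_segment")
  })
}

#' Generate a balanced labelled beat dataset
#'
#' Draws `n_per_class` beats from each of the five default morphologies and
#' (by default) z-normalizes each beat, mirroring the final preprocessing
#' step applied to real traces before classification.
#'
#' @param n_per_class Beats per class (>= 1).
#' @param length Samples per beat (default 186, the classifier input length).
#' @param seed Integer seed; the whole dataset is a pure function of it.
#' @param morphologies List of five morphologies named "0".."4"
#'   (default [default_morphologies()]).
#' @param normalize Z-normalize each beat (default TRUE).
#' @param fs Nominal sampling rate (Hz).
#' @return A `beat_dataset`: list with `beats` (n x length matrix), `labels`
#'   (integer 0..4), `fs`, `split` (character, NA until [assign_splits()]),
#'   and `class_names`.
#' @export
generate_dataset <- function(n_per_class, length = 186L, seed = 0L,
                             morphologies = default_morphologies(),
                             normalize = TRUE, fs = 125) {
  check_count(n_per_class, "n_per_class", lower = 1L)
  check_count(length, "length", lower = 32L)
  if (base::length(morphologies) != 5L) {
    abort_invalid("`morphologies` must list five classes")
  }
  n <- 5L * n_per_class
  labels <- rep(0:4, each = n_per_class)
  beats <- matrix(0, nrow = n, ncol = length)
  # one derived sub-seed per beat so each row is independently reproducible
  sub_seeds <- with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  for (i in seq_len(n)) {
    m <- morphologies[[as.character(labels[i])]]
    beats[i, ] <- generate_beat(m, length, seed = sub_seeds[i], fs = fs)$samples
  }
  if (normalize) {
    beats <- t(apply(beats, 1L, function(r) suppressWarnings(normalize_beat(r))))
  }
  structure(
    list(beats = beats, labels = as.integer(labels), fs = fs,
         split = rep(NA_character_, n), class_names = beat_class_names()),
    class = "beat_dataset"
  )
}

#' Assign stratified train/validation/test split tags
#'
#' @param dataset A `beat_dataset`.
#' @param proportions Named numeric vector summing to 1; default the
#'   package's stratified 80/10/10 policy.
#' @param seed Integer seed for the within-class shuffle.
#' @return The dataset with its `split` field populated.
#' @export
assign_splits <- function(dataset,
                          proportions = c(train = 0.8, val = 0.1, test = 0.1),
                          seed = 0L) {
  stopifnot(inherits(dataset, "beat_dataset"))
  if (abs(sum(proportions) - 1) > 1e-8) {
    abort_invalid("`proportions` must sum to 1")
  }
  split <- rep(NA_character_, base::length(dataset$labels))
  with_local_seed(seed, {
    for (cl in unique(dataset$labels)) {
      idx <- sample(which(dataset$labels == cl))
      n <- base::length(idx)
      bounds <- round(cumsum(proportions) * n)
      starts <- c(1L, head(bounds, -1L) + 1L)
      for (k in seq_along(proportions)) {
        if (starts[k] <= bounds[k]) {
          split[idx[starts[k]:bounds[k]]] <- names(proportions)[k]
        }
      }
    }
  })
  dataset$split <- split
  dataset
}

#' Construct a vitals profile
#'
#' Baseline vitals plus scripted additive episodes, the generator
#' counterpart of one monitored patient.
#'
#' @param baseline_temp_f Baseline body temperature, degrees F.
#' @param baseline_hr_bpm Baseline heart rate, beats per minute.
#' @param baseline_spo2_pct Baseline oxygen saturation, percent (0-100).
#' @param age_years,age_months Patient age.
#' @param episodes List of [vitals_episode()] perturbations.
#' @param jitter_sd Named vector of Gaussian jitter SDs for
#'   `temp_f`, `hr_bpm`, `spo2_pct`.
#' @param interval_s Sampling interval in seconds between readings.
#' @return An object of class `vitals_profile`.
#' @export
vitals_profile <- function(baseline_temp_f = 98.6, baseline_hr_bpm = 72,
                           baseline_spo2_pct = 97, age_years = 30L,
                           age_months = 0L, episodes = list(),
                           jitter_sd = c(temp_f = 0.1, hr_bpm = 1.5,
                                         spo2_pct = 0.3),
                           interval_s = 1.0) {
  check_scalar_number(baseline_spo2_pct, "baseline_spo2_pct", 0, 100)
  check_scalar_number(baseline_temp_f, "baseline_temp_f")
  check_scalar_number(baseline_hr_bpm, "baseline_hr_bpm", lower = 1)
  check_count(age_years, "age_years", lower = 0L)
  check_count(age_months, "age_months", lower = 0L)
  for (ep in episodes) {
    if (!inherits(ep, "vitals_episode")) {
      abort_invalid("`episodes` must be a list of vitals_episode objects")
    }
  }
  structure(
    list(baseline_temp_f = baseline_temp_f,
         baseline_hr_bpm = baseline_hr_bpm,
         baseline_spo2_pct = baseline_spo2_pct,
         age_years = as.integer(age_years),
         age_months = as.integer(age_months),
         episodes = episodes,
         jitter_sd = jitter_sd,
         interval_s = interval_s),
    class = "vitals_profile"
  )
}

#' Define an additive vitals episode
#'
#' @param start_index,end_index 1-based inclusive sample range.
#' @param vital One of "temp_f", "hr_bpm", "spo2_pct".
#' @param offset Additive offset applied over the range.
#' @return An object of class `vitals_episode`.
#' @export
vitals_episode <- function(start_index, end_index, vital, offset) {
  check_count(start_index, "start_index", lower = 1L)
  check_count(end_index, "end_index", lower = 1L)
  if (end_index < start_index) abort_invalid("episode end before start")
  vital <- match.arg(vital, c("temp_f", "hr_bpm", "spo2_pct"))
  check_scalar_number(offset, "offset")
  structure(list(start_index = as.integer(start_index),
                 end_index = as.integer(end_index),
                 vital = vital, offset = offset),
            class = "vitals_episode")
}

#' Generate a vitals telemetry stream
#'
#' Baseline values plus Gaussian jitter, with episode offsets applied
#' additively over their index ranges. Timestamps are strictly increasing.
#'
#' @param profile A [vitals_profile()].
#' @param n_samples Number of readings (>= 1).
#' @param seed Integer seed.
#' @param t0 Timestamp of the first reading (seconds).
#' @return A data.frame with columns `timestamp`, `temp_f`, `hr_bpm`,
#'   `spo2_pct`, `age_years`, `age_months`, one row per reading.
#' @export
generate_vitals_stream <- function(profile, n_samples, seed = 0L, t0 = 0) {
  stopifnot(inherits(profile, "vitals_profile"))
  check_count(n_samples, "n_samples", lower = 1L)
  for (ep in profile$episodes) {
    if (ep$end_index > n_samples) {
      abort_invalid(sprintf(
        "episode range [%d, %d] exceeds n_samples = %d",
        ep$start_index, ep$end_index, n_samples))
    }
  }
  with_local_seed(seed, {
    js <- profile$jitter_sd
    temp <- profile$baseline_temp_f + rnorm(n_samples, 0, js[["temp_f"]])
    hr <- profile$baseline_hr_bpm + rnorm(n_samples, 0, js[["hr_bpm"]])
    spo2 <- profile$baseline_spo2_pct + rnorm(n_samples, 0, js[["spo2_pct"]])
    for (ep in profile$episodes) {
      rng <- ep$start_index:ep$end_index
      if (ep$vital == "temp_f") temp[rng] <- temp[rng] + ep$offset
      if (ep$vital == "hr_bpm") hr[rng] <- hr[rng] + ep$offset
      if (ep$vital == "spo2_pct") spo2[rng] <- spo2[rng] + ep$offset
    }
    data.frame(
      timestamp = t0 + (seq_len(n_samples) - 1L) * profile$interval_s,
      temp_f = temp, hr_bpm = hr, spo2_pct = pmin(spo2, 100),
      age_years = profile$age_years, age_months = profile$age_months
    )
  })
}

#' Nearest-centroid baseline classifier
#'
#' Trains class-mean templates on one dataset and classifies another by
#' Euclidean distance. Used as an independent learnability calibration for
#' the synthetic generator: if this trivial classifier succeeds, the classes
#' are separable and neural-network results are meaningful.
#'
#' @param train_set,test_set `beat_dataset` objects with equal beat length.
#' @return List with `predictions` (integer labels for `test_set`) and
#'   `accuracy`.
#' @export
nearest_centroid <- function(train_set, test_set) {
  stopifnot(inherits(train_set, "beat_dataset"),
            inherits(test_set, "beat_dataset"))
  classes <- sort(unique(train_set$labels))
  centroids <- t(vapply(classes, function(cl) {
    colMeans(train_set$beats[train_set$labels == cl, , drop = FALSE])
  }, numeric(ncol(train_set$beats))))
  x <- test_set$beats
  # squared Euclidean distance via ||x||^2 - 2 x.c + ||c||^2
  d <- outer(rowSums(x^2), rowSums(centroids^2), "+") - 2 * x %*% t(centroids)
  pred <- classes[max.col(-d, ties.method = "first")]
  list(predictions = as.integer(pred),
       accuracy = mean(pred == test_set$labels))
}
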