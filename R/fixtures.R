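# Seeded synthetic 12-lead ECG generator with known ground truth.
# Stands in for a real ECG archive so the full pipeline is testable offline:
# quasi-periodic beats (narrow QRS-like spike + broader T-like bump), a fixed
# per-lead projection, paired pseudo-reports whose rate token follows the
# clinical 60/100 bpm convention, and sex/age covariates.

#' Standard 12-lead names in conventional order
#' @export
ECG_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
               "V1", "V2", "V3", "V4", "V5", "V6")

# fixed per-lead amplitude projection (aVR conventionally negative)
.lead_projection <- c(0.6, 1.0, 0.5, -0.9, 0.4, 0.8,
                      0.7, 0.9, 1.1, 1.0, 0.9, 0.8)

#' Default morphology classes for the synthetic generator
#'
#' Each class is a parameter bundle: QRS-like spike width (s, Gaussian sd) and
#' amplitude (mV), T-like bump amplitude and sign, and baseline-wander
#' amplitude (mV).
#' @export
default_morphologies <- function() {
  # qrs_width is the Gaussian sd in seconds; sd 0.022 gives ~50 ms FWHM,
  # matching a physiological 80-100 ms QRS duration
  list(
    normal     = list(qrs_width = 0.022, qrs_amp = 1.0, t_amp = 0.25,
                      t_sign = 1, wander = 0.05),
    wide_qrs   = list(qrs_width = 0.035, qrs_amp = 0.8, t_amp = 0.20,
                      t_sign = 1, wander = 0.05),
    inverted_t = list(qrs_width = 0.022, qrs_amp = 1.0, t_amp = 0.30,
                      t_sign = -1, wander = 0.05)
  )
}

#' Construct a 12-lead ECG record
#'
#' Light S3 container for one fixed-length 12-lead signal plus metadata.
#' Validates the core invariants: exactly 12 finite signal rows, 12 unique
#' lead names, plausible heart rate when present.
#'
#' @param signal numeric matrix, 12 x L, millivolts.
#' @param fs sampling rate in Hz.
#' @param record_id,patient_id opaque identifiers.
#' @param reports character vector of free-text report strings (may be empty).
#' @param rr_ms machine-reported RR interval in ms, or NA.
#' @param sex "F"/"M" or NA; @param age years or NA;
#' @param heart_rate bpm or NA.
#' @param lead_names character vector of 12 unique lead labels.
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(signal, fs, record_id = "rec", patient_id = "pat",
                       reports = character(), rr_ms = NA_real_,
                       sex = NA_character_, age = NA_real_,
                       heart_rate = NA_real_, lead_names = ECG_LEADS) {
  signal <- as.matrix(signal)
  if (nrow(signal) != 12L) stop("signal must have exactly 12 rows (leads)")
  if (!all(is.finite(signal))) stop("signal entries must be finite")
  if (length(lead_names) != 12L || anyDuplicated(lead_names))
    stop("lead_names must be 12 unique labels")
  if (!is.na(heart_rate) && (heart_rate <= 0 || heart_rate >= 300))
    stop("heart_rate must lie in (0, 300) bpm")
  if (!is.na(sex) && !sex %in% c("F", "M")) stop("sex must be 'F' or 'M'")
  structure(list(signal = signal, fs = fs, lead_names = lead_names,
                 record_id = record_id, patient_id = patient_id,
                 reports = reports, rr_ms = rr_ms, sex = sex, age = age,
                 heart_rate = heart_rate),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s> 12 x %d @ %g Hz; hr=%s bpm; sex=%s age=%s; %d report(s)\n",
              x$record_id, ncol(x$signal), x$fs,
              ifelse(is.na(x$heart_rate), "NA", format(round(x$heart_rate, 1))),
              x$sex, ifelse(is.na(x$age), "NA", x$age), length(x$reports)))
  invisible(x)
}

#' Synthesize one 12-lead ECG-like signal with planted beats
#'
#' Beats are placed at intervals of 60/hr seconds with small seeded jitter
#' (< 2 percent of the interval). Each beat is a narrow positive Gaussian
#' (QRS-like) plus a delayed broader bump (T-like); the single-channel beat
#' train is projected to 12 leads by a fixed amplitude vector, then baseline
#' wander and white Gaussian noise are added.
#'
#' @param hr target beat rate, bpm; must lie within (30, 200).
#' @param morphology a parameter bundle as in [default_morphologies()], or
#'   the name of one of the default classes.
#' @param fs sampling rate (Hz). @param duration length (s).
#' @param noise_sd white-noise standard deviation (mV).
#' @param seed integer seed; identical arguments give identical signals.
#' @return list with `signal` (12 x fs*duration matrix, mV) and `beat_times`
#'   (seconds, the planted QRS centres).
#' @export
synth_ecg <- function(hr, morphology = "normal", fs = 500, duration = 10,
                      noise_sd = 0.03, seed = 1) {
  if (hr <= 30 || hr >= 200) stop("hr out of supported range (30, 200) bpm")
  if (is.character(morphology)) {
    morphology <- default_morphologies()[[match.arg(morphology,
                                          names(default_morphologies()))]]
  }
  m <- morphology
  n <- round(fs * duration)
  tt <- (seq_len(n) - 1) / fs
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  period <- 60 / hr
  # planted beat centres with <2% multiplicative jitter
  n_beats <- ceiling(duration / period) + 2L
  jit <- 1 + pmax(pmin(stats::rnorm(n_beats, 0, 0.008), 0.019), -0.019)
  gaps <- period * jit
  beat_times <- stats::runif(1, 0.1, 0.1 + period) + cumsum(c(0, gaps))
  beat_times <- beat_times[beat_times < duration - 0.05]

  base <- numeric(n)
  for (bt in beat_times) {
    base <- base + m$qrs_amp * exp(-0.5 * ((tt - bt) / m$qrs_width)^2)
    base <- base + m$t_sign * m$t_amp *
      exp(-0.5 * ((tt - (bt + 0.30 * period)) / (0.06 + 0.04 * period))^2)
  }
  wander <- m$wander * sin(2 * pi * 0.25 * tt + stats::runif(1, 0, 2 * pi))
  sig <- outer(.lead_projection, base) +
    matrix(rep(wander, each = 12), 12, n) * stats::runif(12, 0.6, 1.4) +
    matrix(stats::rnorm(12 * n, 0, noise_sd), 12, n)
  rownames(sig) <- ECG_LEADS
  list(signal = sig, beat_times = beat_times)
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# clinical rate bands: <60 bradycardia, 60-100 normal, >100 tachycardia
rate_token <- function(hr) {
  if (hr < 60) "sinus bradycardia" else if (hr <= 100) "sinus rhythm"
  else "sinus tachycardia"
}

morphology_token <- function(name) {
  c(normal = "normal ECG", wide_qrs = "wide QRS complex",
    inverted_t = "T wave inversion")[[name]]
}

#' Generate a seeded synthetic ECG dataset with ground truth
#'
#' Draws heart rates uniformly over `hr_range`, assigns morphology classes
#' uniformly, samples sex ~ Bernoulli(0.5) over {F, M} and age uniformly on
#' 20..90 (integer years), sets `rr_ms = 60000/hr`, and writes a two-token
#' report per record: a rate term following the 60/100 bpm clinical bands
#' ("sinus bradycardia" / "sinus rhythm" / "sinus tachycardia") plus one
#' morphology term.
#'
#' @param n_records number of records (>= 1).
#' @param hr_range bpm range, within (30, 200); default 40-160.
#' @param fs sampling rate (Hz). @param duration seconds.
#' @param morphologies named list of morphology bundles.
#' @param noise_sd white-noise sd (mV). @param seed integer seed.
#' @return list with `records` (list of [ecg_record]) and `truth`
#'   (data.frame: record_id, hr, morphology, n_beats, sex, age).
#' @export
synth_dataset <- function(n_records, hr_range = c(40, 160), fs = 500,
                          duration = 10, morphologies = default_morphologies(),
                          noise_sd = 0.03, seed = 1) {
  stopifnot(n_records >= 1, hr_range[1] > 30, hr_range[2] < 200,
            hr_range[1] < hr_range[2])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  hrs <- stats::runif(n_records, hr_range[1], hr_range[2])
  cls <- sample(names(morphologies), n_records, replace = TRUE)
  sexes <- sample(c("F", "M"), n_records, replace = TRUE)
  ages <- sample(20:90, n_records, replace = TRUE)
  sub_seeds <- sample.int(.Machine$integer.max %/% 2L, n_records)

  records <- vector("list", n_records)
  nb <- integer(n_records)
  for (i in seq_len(n_records)) {
    s <- synth_ecg(hrs[i], morphologies[[cls[i]]], fs = fs,
                   duration = duration, noise_sd = noise_sd,
                   seed = sub_seeds[i])
    nb[i] <- length(s$beat_times)
    records[[i]] <- ecg_record(
      s$signal, fs = fs,
      record_id = sprintf("syn%05d", i), patient_id = sprintf("p%05d", i),
      reports = c(rate_token(hrs[i]), morphology_token(cls[i])),
      rr_ms = 60000 / hrs[i], sex = sexes[i], age = ages[i])
  }
  list(records = records,
       truth = data.frame(record_id = vapply(records, `[[`, "", "record_id"),
                          hr = hrs, morphology = cls, n_beats = nb,
                          sex = sexes, age = ages,
                          stringsAsFactors = FALSE))
}
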