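# Data curation for 12-lead ECG records: heart rate from the machine RR
# interval when it is physiologically valid (300-1500 ms), otherwise from a
# QRS detector run on the waveform itself; records missing heart rate, sex
# or age are discarded; signals are downsampled 5000 -> 1024 samples by
# polyphase resampling and min-max normalized to [-1, 1] for model input.

#' Preprocessing configuration
#'
#' @param rr_valid_range accepted machine RR interval range (ms).
#' @param target_length samples per lead after downsampling.
#' @param source_length expected samples per lead before downsampling.
#' @param source_fs native sampling rate (Hz).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(rr_valid_range = c(300, 1500),
                              target_length = 1024L,
                              source_length = 5000L,
                              source_fs = 500) {
  stopifnot(rr_valid_range[1] > 0, rr_valid_range[1] < rr_valid_range[2],
            target_length > 0, target_length <= source_length)
  structure(list(rr_valid_range = rr_valid_range,
                 target_length = as.integer(target_length),
                 source_length = as.integer(source_length),
                 source_fs = source_fs),
            class = "preprocess_config")
}

#' Heart rate from an RR interval
#'
#' @param rr_ms RR interval in milliseconds (> 0).
#' @return beats per minute, `60000 / rr_ms`.
#' @export
heart_rate_from_rr <- function(rr_ms) {
  if (any(!is.finite(rr_ms)) || any(rr_ms <= 0))
    stop("rr_ms must be positive and finite")
  60000 / rr_ms
}

# beat detection on one lead: band-pass energy envelope, adaptive threshold,
# refractory merging. Returns beat sample indices (possibly empty).
detect_beats <- function(x, fs) {
  n <- length(x)
  if (n < fs || stats::sd(x) < 1e-8) return(integer())
  hi <- min(30, 0.45 * fs)   # QRS energy band; cap below Nyquist
  lo <- 5
  if (lo >= hi) return(integer())
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  bp <- tryCatch(signal::filtfilt(bf, x), error = function(e) NULL)
  if (is.null(bp) || !all(is.finite(bp))) return(integer())
  w <- max(3L, round(0.10 * fs))
  env <- stats::filter(abs(bp), rep(1 / w, w), sides = 2)
  env[is.na(env)] <- 0
  env <- as.numeric(env)
  thr <- 0.45 * stats::quantile(env, 0.995, names = FALSE)
  if (thr <= 0) return(integer())
  # local maxima above threshold
  cand <- which(env > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[env[cand] >= env[cand - 1] & env[cand] >= env[cand + 1]]
  if (!length(cand)) return(integer())
  # refractory merge (0.25 s): keep the strongest peak in each cluster
  refr <- round(0.25 * fs)
  keep <- integer()
  i <- 1L
  while (i <= length(cand)) {
    j <- i
    while (j < length(cand) && cand[j + 1] - cand[i] <= refr) j <- j + 1L
    grp <- cand[i:j]
    keep <- c(keep, grp[which.max(env[grp])])
    i <- j + 1L
  }
  keep
}

#' Heart rate estimated from the waveform
#'
#' Runs a QRS-onset detector on every lead; a lead contributes a rate iff it
#' yields at least two detections with a positive median inter-beat interval
#' (rate = 60 / median interval, restricted to a plausible 20-250 bpm). The
#' record-level rate is the median over contributing leads; `NA` if all 12
#' leads fail.
#'
#' @param record an [ecg_record] (native sampling rate in `record$fs`).
#' @return bpm, or `NA_real_`.
#' @export
heart_rate_from_waveform <- function(record) {
  fs <- record$fs
  rates <- rep(NA_real_, 12)
  for (l in seq_len(12)) {
    beats <- detect_beats(record$signal[l, ], fs)
    if (length(beats) >= 2) {
      iv <- stats::median(diff(beats)) / fs
      if (is.finite(iv) && iv > 0) {
        r <- 60 / iv
        if (r >= 20 && r <= 250) rates[l] <- r
      }
    }
  }
  if (all(is.na(rates))) NA_real_ else stats::median(rates, na.rm = TRUE)
}

#' Resolve a record's heart rate (RR interval with waveform fallback)
#'
#' The machine RR interval is used when it falls inside the valid range
#' (default 300-1500 ms; anomalies such as 0 ms or 65535 ms fall outside);
#' otherwise the rate is estimated from the waveform. If both fail the
#' heart rate stays `NA`.
#'
#' @param record an [ecg_record].
#' @param cfg a [preprocess_config()].
#' @return the record with `heart_rate` populated (or `NA`).
#' @export
resolve_heart_rate <- function(record, cfg = preprocess_config()) {
  rr <- record$rr_ms
  if (!is.na(rr) && rr >= cfg$rr_valid_range[1] && rr <= cfg$rr_valid_range[2]) {
    record$heart_rate <- heart_rate_from_rr(rr)
  } else {
    record$heart_rate <- heart_rate_from_waveform(record)
  }
  record
}

#' Filter records with complete heart rate, sex and age
#'
#' Keeps exactly the records whose heart_rate, sex and age are all present;
#' input order is preserved. Idempotent.
#'
#' @param records list of [ecg_record]s (after [resolve_heart_rate()]).
#' @return filtered list.
#' @export
filter_records <- function(records) {
  keep <- vapply(records, function(r) {
    !is.na(r$heart_rate) && !is.na(r$sex) && !is.na(r$age)
  }, logical(1))
  records[keep]
}

#' Downsample a record to the model input length
#'
#' Anti-aliased resampling of every lead from `cfg$source_length` to
#' `cfg$target_length` samples: a zero-phase Butterworth low-pass at 90% of
#' the new Nyquist frequency (forward-backward filtering, so no phase shift
#' or startup transient) followed by cubic-spline evaluation on the target
#' grid. Constants are preserved exactly; the sampling rate is rescaled by
#' the length ratio.
#'
#' @param record an [ecg_record] of length `cfg$source_length`.
#' @param cfg a [preprocess_config()].
#' @return the record with a 12 x target_length signal.
#' @export
downsample_record <- function(record, cfg = preprocess_config()) {
  L <- ncol(record$signal)
  if (L != cfg$source_length)
    stop(sprintf("record length %d != expected source length %d",
                 L, cfg$source_length))
  ratio <- cfg$target_length / cfg$source_length
  bf <- signal::butter(8, 0.9 * ratio, type = "low")
  grid <- seq(1, L, length.out = cfg$target_length)
  out <- t(apply(record$signal, 1, function(x) {
    xl <- signal::filtfilt(bf, x - x[1]) + x[1]   # remove DC before filtering
    stats::spline(seq_len(L), xl, xout = grid)$y
  }))
  record$signal <- out
  record$fs <- record$fs * ratio
  record
}

#' Min-max normalize a signal to [-1, 1]
#'
#' Per-record affine map; the parameters are returned so the map can be
#' inverted after generation.
#'
#' @param signal numeric matrix (leads x samples).
#' @return list with `signal` in [-1, 1], `center`, `half_range`.
#' @export
normalize_signal <- function(signal) {
  lo <- min(signal); hi <- max(signal)
  center <- (hi + lo) / 2
  half <- (hi - lo) / 2
  if (half <= 0) half <- 1
  list(signal = (signal - center) / half, center = center, half_range = half)
}

#' Invert [normalize_signal()]
#' @param signal normalized matrix. @param center,half_range stored affine
#'   parameters.
#' @return matrix in original units.
#' @export
denormalize_signal <- function(signal, center, half_range) {
  signal * half_range + center
}

#' Run the full curation pipeline on a list of records
#'
#' resolve heart rate -> filter (heart rate, sex, age present) ->
#' downsample -> min-max normalize. Returns the model-ready dataset.
#'
#' @param records list of [ecg_record]s at the native rate/length.
#' @param cfg a [preprocess_config()].
#' @return list: `x` array [12, target_length, N] in [-1,1], `heart_rate`,
#'   `sex`, `age`, `reports` (list), `norm` (data.frame center/half_range),
#'   `records` (the kept, downsampled records), `fs` (post-downsampling Hz).
#' @export
preprocess_records <- function(records, cfg = preprocess_config()) {
  records <- lapply(records, resolve_heart_rate, cfg = cfg)
  records <- filter_records(records)
  if (!length(records)) stop("no records survived filtering")
  records <- lapply(records, downsample_record, cfg = cfg)
  N <- length(records)
  x <- array(0, dim = c(12, cfg$target_length, N))
  center <- half <- numeric(N)
  for (i in seq_len(N)) {
    nm <- normalize_signal(records[[i]]$signal)
    x[, , i] <- nm$signal
    center[i] <- nm$center; half[i] <- nm$half_range
  }
  list(x = x,
       heart_rate = vapply(records, `[[`, 0, "heart_rate"),
       sex = vapply(records, `[[`, "", "sex"),
       age = vapply(records, `[[`, 0, "age"),
       reports = lapply(records, `[[`, "reports"),
       norm = data.frame(center = center, half_range = half),
       records = records,
       fs = records[[1]]$fs)
}
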