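# Curation rules: RR-based heart rate with detector fallback, completeness
# filtering, polyphase downsampling and normalization.

test_that("heart rate from RR follows 60000/rr and is involutive", {
  expect_equal(heart_rate_from_rr(1000), 60)
  expect_equal(heart_rate_from_rr(750), 80)
  expect_equal(heart_rate_from_rr(600), 100)
  expect_error(heart_rate_from_rr(0), "positive")
  expect_error(heart_rate_from_rr(-10), "positive")
  for (h in c(40, 55.5, 72, 160)) {
    expect_equal(heart_rate_from_rr(60000 / h), h)
  }
})

test_that("waveform heart rate recovers planted rates within 2 bpm", {
  for (hr in c(55, 80, 120)) {
    s <- synth_ecg(hr, seed = hr)
    r <- ecg_record(s$signal, fs = 500)
    # oracle: the planted beat count over the observed beat span
    planted <- 60 * (length(s$beat_times) - 1) /
      (max(s$beat_times) - min(s$beat_times))
    est <- heart_rate_from_waveform(r)
    expect_lt(abs(est - planted), 2)
    expect_lt(abs(est - hr), 2)
  }
  zero <- ecg_record(matrix(0, 12, 5000), fs = 500)
  expect_true(is.na(heart_rate_from_waveform(zero)))
})

test_that("heart-rate resolution prefers valid RR and falls back to the detector", {
  s <- synth_ecg(80, seed = 2)
  # anomalous 65535 ms RR: detector fallback should find ~80 bpm
  r <- ecg_record(s$signal, fs = 500, rr_ms = 65535)
  expect_lt(abs(resolve_heart_rate(r)$heart_rate - 80), 2)
  # in-range RR wins even when the waveform disagrees
  r2 <- ecg_record(s$signal, fs = 500, rr_ms = 1000)
  expect_equal(resolve_heart_rate(r2)$heart_rate, 60)
  # double failure: 0 ms RR and a flat signal
  r3 <- ecg_record(matrix(0, 12, 5000), fs = 500, rr_ms = 0)
  expect_true(is.na(resolve_heart_rate(r3)$heart_rate))
})

test_that("filtering keeps exactly the complete records, in order, idempotently", {
  s <- synth_ecg(70, seed = 3)
  complete <- ecg_record(s$signal, fs = 500, record_id = "a", rr_ms = 857,
                         sex = "F", age = 40)
  complete <- resolve_heart_rate(complete)
  no_age <- ecg_record(s$signal, fs = 500, record_id = "b", rr_ms = 857,
                       sex = "M")
  no_age <- resolve_heart_rate(no_age)
  no_hr <- ecg_record(matrix(0, 12, 5000), fs = 500, record_id = "c",
                      rr_ms = 0, sex = "F", age = 30)
  no_hr <- resolve_heart_rate(no_hr)

  kept <- filter_records(list(complete, no_age, no_hr))
  expect_length(kept, 1L)
  expect_identical(kept[[1]]$record_id, "a")
  expect_identical(filter_records(kept), kept)
  expect_length(filter_records(list()), 0L)
  five <- replicate(5, complete, simplify = FALSE)
  expect_length(filter_records(five), 5L)
})

test_that("downsampling yields 1024 samples and preserves low-frequency content", {
  s <- synth_ecg(70, seed = 4)
  r <- ecg_record(s$signal, fs = 500, rr_ms = 857, sex = "F", age = 40)
  d <- downsample_record(r)
  expect_equal(dim(d$signal), c(12L, 1024L))
  expect_equal(d$fs, 500 * 1024 / 5000)

  # constants resample to the same constant
  rc <- ecg_record(matrix(2.5, 12, 5000), fs = 500)
  dc <- downsample_record(rc)
  expect_lt(max(abs(dc$signal - 2.5)), 1e-6)

  # a pure 1 Hz sinusoid keeps its dominant frequency
  tt <- (0:4999) / 500
  sig <- matrix(rep(sin(2 * pi * tt), each = 12), 12, 5000)
  dsin <- downsample_record(ecg_record(sig, fs = 500))
  sp <- Mod(fft(dsin$signal[1, ]))[2:512]
  expect_equal(which.max(sp), 10L)   # bin 10 = 1 Hz over a 10 s window

  # band-limited fixture: per-lead mean preserved within 1% of signal scale
  lo <- synth_ecg(50, noise_sd = 0, seed = 5)
  dl <- downsample_record(ecg_record(lo$signal, fs = 500))
  scale <- max(abs(lo$signal))
  expect_lt(max(abs(rowMeans(dl$signal) - rowMeans(lo$signal))), 0.01 * scale)

  expect_error(downsample_record(ecg_record(matrix(0, 12, 400), fs = 500)),
               "length")
})

test_that("normalization maps to [-1, 1] and inverts exactly", {
  s <- synth_ecg(90, seed = 6)
  nm <- normalize_signal(s$signal)
  expect_equal(range(nm$signal), c(-1, 1))
  back <- denormalize_signal(nm$signal, nm$center, nm$half_range)
  expect_lt(max(abs(back - s$signal)), 1e-12)
})

test_that("the full pipeline returns a model-ready container", {
  ds0 <- synth_dataset(6, seed = 7)
  ds <- preprocess_records(ds0$records)
  expect_equal(dim(ds$x)[1:2], c(12L, 1024L))
  expect_equal(dim(ds$x)[3], 6L)
  expect_true(all(abs(ds$x) <= 1))
  expect_length(ds$heart_rate, 6L)
  expect_true(all(ds$sex %in% c("F", "M")))
})
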