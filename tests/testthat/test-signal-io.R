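test_that("WAV round trip preserves samples to 16-bit quantisation", {
  cfg <- synthesis_config(duration_s = 5, sampling_rate = 2000, seed = 11)
  rec <- synthesize_pcg(cfg, "normal")
  rec$samples <- rec$samples / max(abs(rec$samples))  # full-scale
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(rec, path)
  back <- read_wav(path)
  expect_equal(length(back$samples), 10000L)
  expect_equal(back$sampling_rate, 2000)
  expect_null(back$label)
  # write quantises to x*32767, read rescales by 32768: bound 1.5/32768
  expect_lt(max(abs(back$samples - rec$samples)), 1.5 / 32768 + 1e-12)
})

test_that("a 5 s 2000 Hz mono WAV yields 10000 samples; zeros stay zero", {
  rec <- heart_sound_record(numeric(10000) + 0, 2000, "zeros")
  # all-zero records are representable even though features reject them
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(rec, path)
  back <- read_wav(path)
  expect_equal(length(back$samples), 10000L)
  expect_true(all(back$samples == 0))
})

test_that("stereo and corrupt WAV inputs are rejected with clear errors", {
  stereo <- withr::local_tempfile(fileext = ".wav")
  con <- file(stereo, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + 8L, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # two channels
  writeBin(2000L, con, size = 4, endian = "little")
  writeBin(8000L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(8L, con, size = 4, endian = "little")
  writeBin(c(0L, 0L, 0L, 0L), con, size = 2, endian = "little")
  close(con)
  expect_error(read_wav(stereo), "mono required")

  junk <- withr::local_tempfile(fileext = ".wav")
  writeBin(as.raw(1:32), junk)
  expect_error(read_wav(junk), "RIFF")
  expect_error(read_wav(file.path(tempdir(), "absent.wav")), "not found")
})

test_that("32-bit float WAV payloads are read as stored", {
  path <- withr::local_tempfile(fileext = ".wav")
  vals <- c(-0.5, 0.25, 0.125, 1)
  con <- file(path, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 16), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")   # IEEE float
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2000L, con, size = 4, endian = "little")
  writeBin(8000L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(vals, con, size = 4, endian = "little")
  close(con)
  back <- read_wav(path)
  expect_equal(back$samples, vals, tolerance = 1e-7)
})

test_that("window_record truncates, zero-pads, preserves labels, and is idempotent", {
  long <- heart_sound_record(seq_len(12000) / 12000, 2000, "long", "abnormal")
  w <- window_record(long, 10000)
  expect_equal(w$samples, long$samples[1:10000])
  expect_equal(w$label, "abnormal")

  short <- heart_sound_record(rep(1, 8000), 2000, "short", "normal")
  w2 <- window_record(short, 10000)
  expect_equal(length(w2$samples), 10000L)
  expect_true(all(w2$samples[8001:10000] == 0))
  expect_equal(w2$samples[1:8000], short$samples)

  exact <- heart_sound_record(rnorm(10000), 2000, "exact")
  expect_identical(window_record(exact, 10000)$samples, exact$samples)
  # idempotency
  expect_identical(window_record(w, 10000)$samples, w$samples)
  expect_error(window_record(exact, 0), "positive integer")
})

test_that("record construction enforces finite non-empty samples", {
  expect_error(heart_sound_record(numeric(0), 2000), "non-empty")
  expect_error(heart_sound_record(c(1, NA), 2000), "finite")
  expect_error(heart_sound_record(1:5, -1), "positive")
  expect_error(heart_sound_record(1:5, 2000, label = "odd"), "arg")
})

test_that("synthesis is deterministic and a 60 bpm, 5 s record has 5 S1 bursts", {
  cfg <- synthesis_config(heart_rate_bpm = 60, noise_sd = 0,
                          murmur_amplitude = 0, seed = 3)
  a <- synthesize_pcg(cfg, "normal")
  b <- synthesize_pcg(cfg, "normal")
  expect_identical(a$samples, b$samples)
  expect_equal(length(a$samples), 10000L)

  # S1 peaks reach ~1, S2 ~0.8: bursts = clusters of |x| > 0.9
  hot <- which(abs(a$samples) > 0.9)
  bursts <- sum(diff(c(-1000, hot)) > 400)  # clusters >0.2 s apart
  expect_equal(bursts, 5L)
})

test_that("normal and abnormal share everything outside systole", {
  cfg <- synthesis_config(heart_rate_bpm = 60, noise_sd = 0.01,
                          murmur_amplitude = 0.3, seed = 9)
  nrm <- synthesize_pcg(cfg, "normal")
  abn <- synthesize_pcg(cfg, "abnormal")
  d <- abn$samples - nrm$samples
  expect_gt(sum(d^2), 0)
  t <- (seq_along(d) - 1) / cfg$sampling_rate
  # systolic murmur window per beat: [s1_centre + 0.05, s1_centre + systole - 0.04]
  in_systole <- rep(FALSE, length(d))
  for (beat in seq(0, 5, by = 1)) {
    in_systole <- in_systole | (t >= beat + 0.11 & t <= beat + 0.37)
  }
  expect_true(all(d[!in_systole] == 0))
})

test_that("dataset synthesis is reproducible and labelled as requested", {
  r1 <- synthesize_dataset(3, 4, seed = 5)
  r2 <- synthesize_dataset(3, 4, seed = 5)
  expect_identical(lapply(r1, `[[`, "samples"), lapply(r2, `[[`, "samples"))
  expect_equal(vapply(r1, `[[`, "", "label"),
               c(rep("normal", 3), rep("abnormal", 4)))
  r3 <- synthesize_dataset(3, 4, seed = 6)
  expect_false(identical(r1[[1]]$samples, r3[[1]]$samples))
})
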