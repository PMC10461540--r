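# hand-written RIFF fixture, independent of write_wave, so the reader is
# checked against the byte layout rather than against its own writer
write_raw_wav <- function(path, samples_int16, n_channels = 1L, sr = 24000L) {
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- 2L * length(samples_int16)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + nbytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(n_channels, con, size = 2, endian = "little")
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L * n_channels, con, size = 4, endian = "little")
  writeBin(2L * n_channels, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(nbytes, con, size = 4, endian = "little")
  writeBin(as.integer(samples_int16), con, size = 2, endian = "little")
}

test_that("16-bit PCM samples are scaled linearly to [-1, 1]", {
  path <- withr::local_tempfile(fileext = ".wav")
  write_raw_wav(path, c(16384L, -16384L, 0L, 32767L, -32768L))
  w <- read_wave(path)
  expect_equal(w$samples[1], 0.5, tolerance = 1 / 32768)
  expect_equal(w$samples[2], -0.5, tolerance = 1 / 32768)
  expect_identical(w$samples[3], 0)
  expect_equal(w$samples[4], 32767 / 32768)
  expect_identical(w$samples[5], -1)
  expect_identical(w$sample_rate, 24000L)
})

test_that("write then read round-trips within quantisation at each depth", {
  x <- waveform(sin(2 * pi * 440 * (0:23999) / 24000) * 0.9, 24000)
  for (depth in list(16, 24, "float32")) {
    path <- withr::local_tempfile(fileext = ".wav")
    write_wave(path, x, bit_depth = depth)
    y <- read_wave(path)
    expect_identical(y$sample_rate, x$sample_rate)
    expect_length(y$samples, length(x$samples))
    tol <- switch(as.character(depth), "16" = 2 / 32768, "24" = 2 / 8388608,
                  "float32" = 1e-7)
    expect_lt(max(abs(y$samples - x$samples)), tol)
  }
})

test_that("a 1 s 24 kHz sine survives a write/read cycle with exact shape", {
  x <- tone_wave(440, seconds = 1, sr = 24000)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wave(path, x)
  y <- read_wave(path)
  expect_length(y$samples, 24000)
  expect_identical(y$sample_rate, 24000L)
})

test_that("opposite-phase stereo channels average to silence", {
  x <- as.integer(round(sin(2 * pi * 440 * (0:999) / 24000) * 16000))
  interleaved <- as.vector(rbind(x, -x))
  path <- withr::local_tempfile(fileext = ".wav")
  write_raw_wav(path, interleaved, n_channels = 2L)
  w <- read_wave(path)
  expect_length(w$samples, 1000)
  expect_true(all(w$samples == 0))
})

test_that("out-of-range samples are clamped on write with a warning", {
  x <- waveform(c(0.5, 1.7, -2.0), 8000)
  path <- withr::local_tempfile(fileext = ".wav")
  expect_warning(write_wave(path, x), "clipped")
  y <- read_wave(path)
  expect_equal(y$samples[2], 1, tolerance = 2 / 32768)
  expect_equal(y$samples[3], -1, tolerance = 2 / 32768)
})

test_that("invalid waveforms and files are rejected", {
  expect_error(waveform(numeric(0), 8000), "length >= 1")
  expect_error(waveform(c(0, NA), 8000), "finite")
  expect_error(waveform(1:10, 0), "sample_rate")
  expect_error(read_wave(file.path(tempdir(), "no_such_file.wav")),
               "not found")
  path <- withr::local_tempfile(fileext = ".wav")
  writeLines("definitely not audio", path)
  expect_error(read_wave(path), "RIFF")
})

test_that("gain follows the 10^(dB/20) law and is invertible", {
  x <- tone_wave(1000, seconds = 0.1)
  expect_identical(apply_gain(x, 0)$samples, x$samples)
  expect_equal(apply_gain(x, 20)$samples, x$samples * 10)
  expect_equal(apply_gain(x, -20)$samples, x$samples * 0.1)
  y <- apply_gain(apply_gain(x, 7.3), -7.3)
  expect_lt(max(abs(y$samples - x$samples)), 1e-12)
})

test_that("peak normalization scales to unit peak and guards zeros", {
  x <- tone_wave(500, seconds = 0.1, amp = 0.25)
  y <- normalize_peak(x)
  expect_equal(max(abs(y$samples)), 1)
  expect_equal(y$samples * 0.25, x$samples)
  expect_identical(normalize_peak(y)$samples, y$samples)
  z <- waveform(numeric(100) + 0, 8000)
  expect_warning(out <- normalize_peak(z), "all-zero")
  expect_true(all(out$samples == 0))
})

test_that("segmentation tiles the waveform without overlap or gap", {
  x <- tone_wave(440, seconds = 60)
  clips <- segment(x, 15)
  expect_length(clips, 4)
  expect_equal(vapply(clips, function(cl) cl$clip_offset_seconds,
                      numeric(1)), c(0, 15, 30, 45))
  expect_true(all(vapply(clips, function(cl) duration(cl$waveform),
                         numeric(1)) == 15))

  x35 <- tone_wave(440, seconds = 35)
  clips35 <- segment(x35, 15)
  expect_equal(vapply(clips35, function(cl) duration(cl$waveform),
                      numeric(1)), c(15, 15, 5))

  x10 <- tone_wave(440, seconds = 10)
  expect_length(segment(x10, 15), 1)

  glued <- unlist(lapply(clips35, function(cl) cl$waveform$samples))
  expect_identical(glued, x35$samples)
})

test_that("recorder filenames parse per the convention", {
  id <- parse_filename("RAHORA_20220415_063000.wav")
  expect_identical(id$recorder, "RAHORA")
  expect_identical(format(id$start_datetime, "%Y-%m-%d %H:%M:%S",
                          tz = "UTC"), "2022-04-15 06:30:00")
  expect_identical(id$offset_seconds, 0L)

  id2 <- parse_filename("TEEVURCHER_20220501_220000_start_05_30.wav")
  expect_identical(id2$offset_seconds, 330L)

  expect_warning(res <- parse_filename("notes.txt"), "does not match")
  expect_null(res)
  expect_warning(parse_filename("REC_20220230_250000.wav"), "invalid")
})

test_that("identities format to canonical names and round-trip", {
  id <- recording_identity("RAHORA",
                           as.POSIXct("2022-04-15 06:30:00", tz = "UTC"))
  expect_identical(format_filename(id), "RAHORA_20220415_063000.wav")

  id2 <- recording_identity("RICHFIELDM1",
                            as.POSIXct("2022-06-01 00:00:00", tz = "UTC"),
                            90L)
  expect_identical(format_filename(id2),
                   "RICHFIELDM1_20220601_000000_start_01_30.wav")

  expect_error(format_filename(
    recording_identity("A", as.POSIXct("2022-01-01", tz = "UTC"), 3600L)),
    "MM_SS")

  set.seed(42)
  for (i in 1:100) {
    rec <- paste(sample(LETTERS, sample(3:12, 1), replace = TRUE),
                 collapse = "")
    dt <- as.POSIXct("2020-01-01", tz = "UTC") +
      sample.int(4 * 365 * 86400, 1)
    off <- sample(0:3599, 1)
    id <- recording_identity(rec, dt, off)
    back <- parse_filename(format_filename(id))
    expect_identical(back$recorder, id$recorder)
    expect_true(back$start_datetime == id$start_datetime)
    expect_identical(back$offset_seconds, id$offset_seconds)
  }
})
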