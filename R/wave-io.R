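#' Read a WAV file as a mono waveform
#'
#' Reads RIFF/WAVE files containing integer PCM (16-, 24- or 32-bit) or IEEE
#' float (32- or 64-bit) samples. Samples are scaled to \[-1, 1\] by the
#' full-scale value of the storage format. Multi-channel files are mixed down
#' to mono by averaging the channels.
#'
#' @param path Path to an existing `.wav` file.
#' @return A [waveform()].
#' @export
read_wave <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("WAV file not found: '%s'", path), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop(sprintf("'%s' is not a RIFF/WAVE file", path), call. = FALSE)
  }

  fmt <- NULL
  data_raw <- NULL
  # walk chunks until both fmt and data have been seen
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(size) == 0) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, signed = FALSE,
                               endian = "little"),
        n_channels   = readBin(body[3:4], "integer", 1, 2, signed = FALSE,
                               endian = "little"),
        sample_rate  = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1, 2, signed = FALSE,
                               endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2 == 1) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop(sprintf("'%s' is missing its fmt or data chunk", path), call. = FALSE)
  }

  x <- decode_wav_samples(data_raw, fmt$audio_format, fmt$bits)
  nch <- fmt$n_channels
  if (nch > 1) {
    usable <- (length(x) %/% nch) * nch
    x <- colMeans(matrix(x[seq_len(usable)], nrow = nch))
  }
  waveform(x, fmt$sample_rate)
}

# data chunk bytes -> numeric samples in [-1, 1]
decode_wav_samples <- function(raw, audio_format, bits) {
  if (audio_format == 1L) {  # integer PCM
    if (bits == 16L) {
      readBin(raw, "integer", length(raw) %/% 2, size = 2,
              endian = "little") / 32768
    } else if (bits == 24L) {
      n <- length(raw) %/% 3
      b <- matrix(as.integer(raw[seq_len(3 * n)]), nrow = 3)
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    } else if (bits == 32L) {
      readBin(raw, "integer", length(raw) %/% 4, size = 4,
              endian = "little") / 2147483648
    } else {
      stop(sprintf("unsupported PCM bit depth: %d", bits), call. = FALSE)
    }
  } else if (audio_format == 3L) {  # IEEE float
    if (bits == 32L) {
      readBin(raw, "numeric", length(raw) %/% 4, size = 4, endian = "little")
    } else if (bits == 64L) {
      readBin(raw, "numeric", length(raw) %/% 8, size = 8, endian = "little")
    } else {
      stop(sprintf("unsupported float bit depth: %d", bits), call. = FALSE)
    }
  } else {
    stop(sprintf("unsupported WAV audio format code: %d", audio_format),
         call. = FALSE)
  }
}

#' Write a waveform to a WAV file
#'
#' Writes integer PCM (16 or 24 bit) or 32-bit IEEE float. Samples outside
#' \[-1, 1\] are clamped with a warning; clamping at write time (rather than in
#' the processing chain) is deliberate, so gains applied in memory are
#' lossless until export.
#'
#' @param path Output file path.
#' @param waveform A [waveform()] object.
#' @param bit_depth One of 16 (default), 24, or "float32".
#' @return `path`, invisibly.
#' @export
write_wave <- function(path, waveform, bit_depth = 16) {
  stopifnot(inherits(waveform, "waveform"))
  x <- waveform$samples
  if (any(abs(x) > 1)) {
    warning(sprintf("%d sample(s) outside [-1, 1] clipped on write",
                    sum(abs(x) > 1)), call. = FALSE)
    x <- pmin(pmax(x, -1), 1)
  }
  sr <- waveform$sample_rate

  if (identical(bit_depth, "float32")) {
    fmt_code <- 3L; bits <- 32L
    payload_writer <- function(con) writeBin(x, con, size = 4,
                                             endian = "little")
    nbytes <- 4L * length(x)
  } else if (bit_depth == 16) {
    fmt_code <- 1L; bits <- 16L
    q <- as.integer(pmin(pmax(round(x * 32767), -32768), 32767))
    payload_writer <- function(con) writeBin(q, con, size = 2,
                                             endian = "little")
    nbytes <- 2L * length(x)
  } else if (bit_depth == 24) {
    fmt_code <- 1L; bits <- 24L
    q <- pmin(pmax(round(x * 8388607), -8388608), 8388607)
    q <- ifelse(q < 0, q + 16777216, q)
    b <- rbind(q %% 256, (q %/% 256) %% 256, (q %/% 65536) %% 256)
    payload_writer <- function(con) writeBin(as.raw(as.integer(b)), con)
    nbytes <- 3L * length(x)
  } else {
    stop("`bit_depth` must be 16, 24 or \"float32\"", call. = FALSE)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  block_align <- as.integer(bits / 8)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + nbytes + nbytes %% 2), con, size = 4,
           endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(sr), con, size = 4, endian = "little")
  writeBin(as.integer(sr * block_align), con, size = 4, endian = "little")
  writeBin(block_align, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  payload_writer(con)
  if (nbytes %% 2 == 1) writeBin(as.raw(0), con)
  invisible(path)
}
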