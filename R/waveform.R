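#' Construct a waveform
#'
#' A waveform is the unit all filters return to: a mono sequence of amplitude
#' samples nominally in \[-1, 1\] together with its sample rate. Values outside
#' \[-1, 1\] are permitted in memory (e.g. after gain); they are only clamped
#' when written to disk by [write_wave()].
#'
#' @param samples Numeric vector of amplitude samples (length >= 1, all finite).
#' @param sample_rate Sampling rate in Hz (positive integer).
#' @return An object of class `"waveform"`: a list with elements `samples` and
#'   `sample_rate`.
#' @seealso [read_wave()], [write_wave()], [duration()]
#' @export
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 1, length.out = 8000)), 8000)
#' duration(w)
waveform <- function(samples, sample_rate) {
  if (!is.numeric(samples) || length(samples) < 1) {
    stop("`samples` must be a numeric vector of length >= 1", call. = FALSE)
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("`samples` must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 ||
      !is.finite(sample_rate) || sample_rate <= 0 ||
      sample_rate != as.integer(sample_rate)) {
    stop("`sample_rate` must be a positive integer number of Hz", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.integer(sample_rate)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %d Hz (%.3f s), peak %.4f\n",
              length(x$samples), x$sample_rate, duration(x),
              max(abs(x$samples))))
  invisible(x)
}

#' Duration of a waveform in seconds
#'
#' Derived as `length(samples) / sample_rate`; never stored independently.
#'
#' @param waveform A [waveform()] object.
#' @return Duration in seconds.
#' @export
duration <- function(waveform) {
  stopifnot(inherits(waveform, "waveform"))
  length(waveform$samples) / waveform$sample_rate
}

#' Apply decibel gain to a waveform
#'
#' Multiplies every sample by `10^(gain_db / 20)`. No clipping is performed at
#' this stage: samples may leave \[-1, 1\] and are only clamped when written to
#' disk, so information is preserved through a processing chain.
#'
#' @param waveform A [waveform()] object.
#' @param gain_db Gain in dB (finite scalar; 0 is the identity, +20 multiplies
#'   amplitudes by 10, -20 by 0.1).
#' @return A gained [waveform()].
#' @export
apply_gain <- function(waveform, gain_db) {
  stopifnot(inherits(waveform, "waveform"))
  if (!is.numeric(gain_db) || length(gain_db) != 1 || !is.finite(gain_db)) {
    stop("`gain_db` must be a finite scalar", call. = FALSE)
  }
  waveform$samples <- waveform$samples * 10^(gain_db / 20)
  waveform
}

#' Peak-normalize a waveform
#'
#' Rescales so the peak absolute amplitude is exactly 1; the waveform shape is
#' preserved up to a positive scaling. An all-zero input cannot be normalized
#' and is returned unchanged with a warning.
#'
#' @param waveform A [waveform()] object.
#' @return A [waveform()] with peak absolute amplitude 1 (or the unchanged
#'   input if all-zero).
#' @export
normalize_peak <- function(waveform) {
  stopifnot(inherits(waveform, "waveform"))
  peak <- max(abs(waveform$samples))
  if (peak == 0) {
    warning("all-zero waveform cannot be normalized; returned unchanged",
            call. = FALSE)
    return(waveform)
  }
  waveform$samples <- waveform$samples / peak
  waveform
}

#' Segment a waveform into fixed-length clips
#'
#' Splits a recording into consecutive clips of `clip_seconds` each (the
#' annotation display unit; 15 s by default). Clips tile the waveform in order
#' without overlap or gap; the final clip may be shorter. Concatenating the
#' clips reproduces the input exactly.
#'
#' @param waveform A [waveform()] object.
#' @param clip_seconds Clip length in seconds (> 0; default 15).
#' @param source_file Optional source file name recorded on each clip.
#' @return A list of clips; each clip is a list with elements `waveform`
#'   (a [waveform()]), `source_file` and `clip_offset_seconds`
#'   (`index * clip_seconds`), of class `"clip"`.
#' @export
segment <- function(waveform, clip_seconds = 15, source_file = "") {
  stopifnot(inherits(waveform, "waveform"))
  if (!is.numeric(clip_seconds) || length(clip_seconds) != 1 ||
      !is.finite(clip_seconds) || clip_seconds <= 0) {
    stop("`clip_seconds` must be a positive number of seconds", call. = FALSE)
  }
  spc <- round(clip_seconds * waveform$sample_rate)
  if (spc < 1) stop("`clip_seconds` is shorter than one sample", call. = FALSE)
  n <- length(waveform$samples)
  starts <- seq.int(1L, n, by = spc)
  lapply(seq_along(starts), function(i) {
    lo <- starts[i]
    hi <- min(lo + spc - 1L, n)
    structure(list(
      waveform = waveform(waveform$samples[lo:hi], waveform$sample_rate),
      source_file = source_file,
      clip_offset_seconds = (i - 1) * clip_seconds
    ), class = "clip")
  })
}
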