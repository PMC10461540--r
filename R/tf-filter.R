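#' Time-frequency bounding box
#'
#' A rectangle in clip time (seconds) by frequency (kHz), defined by its
#' lower-left and upper-right corners. Used both as a selection geometry for
#' filtering/zooming and as the geometry of a saved annotation.
#'
#' @param t_start,t_end Start/end time in seconds (clip-relative),
#'   `t_start < t_end`, both >= 0.
#' @param f_start,f_end Low/high frequency in kHz, `f_start < f_end`,
#'   both >= 0.
#' @return An object of class `"bounding_box"`.
#' @export
#' @examples
#' bounding_box(3, 6, 0, 5)  # the 3-6 s, 0-5 kHz window
bounding_box <- function(t_start, t_end, f_start, f_end) {
  v <- c(t_start, t_end, f_start, f_end)
  if (!is.numeric(v) || length(v) != 4 || anyNA(v) || any(!is.finite(v))) {
    stop("box coordinates must be four finite numbers", call. = FALSE)
  }
  if (any(v < 0)) stop("box coordinates must be >= 0", call. = FALSE)
  if (t_start >= t_end) stop("`t_start` must be < `t_end`", call. = FALSE)
  if (f_start >= f_end) stop("`f_start` must be < `f_end`", call. = FALSE)
  structure(list(t_start = t_start, t_end = t_end,
                 f_start = f_start, f_end = f_end),
            class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<box> %.3f-%.3f s x %.3f-%.3f kHz\n",
              x$t_start, x$t_end, x$f_start, x$f_end))
  invisible(x)
}

#' Mask specification for selection filtering
#'
#' Controls what happens to spectrogram cells outside a selection. In
#' `"zero"` mode outside magnitudes are multiplied by `epsilon` (exactly 0
#' by default; a small positive epsilon leaves near-zero residue, which can
#' soften reconstruction artefacts). In `"attenuate"` mode outside cells are
#' divided by `attenuation_factor` (default 100), the gentler alternative
#' when fully zeroed audio sounds unnatural.
#'
#' @param box A [bounding_box()] selection.
#' @param mode `"zero"` (default) or `"attenuate"`.
#' @param attenuation_factor Magnitude divisor for outside cells in
#'   attenuate mode (> 1; default 100).
#' @param epsilon Outside-cell multiplier in zero mode (>= 0; default 0).
#' @return An object of class `"mask_spec"`.
#' @export
mask_spec <- function(box, mode = c("zero", "attenuate"),
                      attenuation_factor = 100, epsilon = 0) {
  stopifnot(inherits(box, "bounding_box"))
  mode <- match.arg(mode)
  if (!is.numeric(attenuation_factor) || length(attenuation_factor) != 1 ||
      !is.finite(attenuation_factor) || attenuation_factor <= 1) {
    stop("`attenuation_factor` must be a finite number > 1", call. = FALSE)
  }
  if (!is.numeric(epsilon) || length(epsilon) != 1 || !is.finite(epsilon) ||
      epsilon < 0) {
    stop("`epsilon` must be a finite number >= 0", call. = FALSE)
  }
  structure(list(box = box, mode = mode,
                 attenuation_factor = attenuation_factor, epsilon = epsilon),
            class = "mask_spec")
}

# logical matrix of cells whose centres fall inside the (closed) box
box_membership <- function(cspec, box) {
  ctr <- spectrogram_centres(cspec)
  inside_t <- ctr$time_s >= box$t_start & ctr$time_s <= box$t_end
  inside_f <- ctr$freq_khz >= box$f_start & ctr$freq_khz <= box$f_end
  outer(inside_f, inside_t, `&`)
}

#' Mask a complex spectrogram outside a selection box
#'
#' Cells whose centres lie inside the box are returned bit-identical;
#' outside cells are multiplied by `epsilon` (zero mode) or by
#' `1 / attenuation_factor` (attenuate mode). Because the complex values are
#' scaled, phase is preserved wherever the magnitude remains nonzero, which
#' is what makes the subsequent overlap-add reconstruction coherent.
#'
#' @param cspec A [compute_stft()] result.
#' @param mask A [mask_spec()].
#' @return A masked `"complex_spectrogram"`.
#' @export
apply_box_filter <- function(cspec, mask) {
  stopifnot(inherits(cspec, "complex_spectrogram"),
            inherits(mask, "mask_spec"))
  inside <- box_membership(cspec, mask$box)
  if (!any(inside)) {
    stop("selection box contains no spectrogram cell centres; nothing would remain",
         call. = FALSE)
  }
  mult <- if (mask$mode == "zero") mask$epsilon else 1 / mask$attenuation_factor
  cspec$values[!inside] <- cspec$values[!inside] * mult
  cspec
}

#' Band-pass filter a complex spectrogram
#'
#' Keeps the whole duration but only frequencies within `[f_start, f_end]`:
#' equivalent to [apply_box_filter()] with a box spanning the full time
#' extent. This is the frequency-slider filter of an annotation session.
#'
#' @param cspec A [compute_stft()] result.
#' @param f_start,f_end Band edges in kHz (`f_start < f_end`; the band must
#'   intersect `[0, Nyquist]`).
#' @param mode,attenuation_factor,epsilon Passed to [mask_spec()].
#' @return A masked `"complex_spectrogram"`.
#' @export
apply_band_filter <- function(cspec, f_start, f_end, mode = "zero",
                              attenuation_factor = 100, epsilon = 0) {
  stopifnot(inherits(cspec, "complex_spectrogram"))
  if (!is.numeric(f_start) || !is.numeric(f_end) || f_start >= f_end) {
    stop("`f_start` must be < `f_end` (kHz)", call. = FALSE)
  }
  nyq <- cspec$sample_rate / 2 / 1000
  if (f_end < 0 || f_start > nyq) {
    stop(sprintf("band [%g, %g] kHz does not intersect [0, %g] kHz",
                 f_start, f_end, nyq), call. = FALSE)
  }
  N <- cspec$params$window_length
  hop <- cspec$params$hop
  nf <- ncol(cspec$values)
  t_end <- ((nf - 1) * hop + N) / cspec$sample_rate
  box <- bounding_box(0, t_end, max(f_start, 0), min(f_end, nyq))
  apply_box_filter(cspec, mask_spec(box, mode = mode,
                                    attenuation_factor = attenuation_factor,
                                    epsilon = epsilon))
}

#' Row-wise spectral noise reduction
#'
#' Median-magnitude spectral subtraction per frequency row: for each row the
#' median magnitude over frames estimates the stationary noise level of that
#' frequency band, and is subtracted from every cell's magnitude (floored at
#' zero) with phase preserved. Stationary broadband noise (e.g. wind-turbine
#' hum) is strongly suppressed, while sparse transient vocalisations -
#' present in fewer than half the frames of their rows - pass nearly
#' unchanged. Rows whose median is zero are untouched.
#'
#' @param cspec A [compute_stft()] result with at least 2 frames.
#' @return A noise-reduced `"complex_spectrogram"`.
#' @export
reduce_noise_rowwise <- function(cspec) {
  stopifnot(inherits(cspec, "complex_spectrogram"))
  if (ncol(cspec$values) < 2) {
    stop("noise reduction needs at least 2 frames", call. = FALSE)
  }
  mag <- Mod(cspec$values)
  med <- apply(mag, 1, stats::median)
  newmag <- pmax(mag - med, 0)
  scale <- ifelse(mag > 0, newmag / mag, 0)
  cspec$values <- cspec$values * scale
  cspec
}

#' Reconstruct audio from a (possibly masked) complex spectrogram
#'
#' Weighted overlap-add inverse STFT: each half-spectrum column is extended
#' to a full conjugate-symmetric spectrum (the absent Nyquist bin is taken
#' as zero), inverse-FFT'd, multiplied by the analysis window used as
#' synthesis window, overlap-added, and normalized by the summed squared
#' window. The output has `(frames - 1) * hop + N` samples; callers that
#' need the original length must pad or truncate explicitly.
#'
#' Requires `overlap >= 0.5` (hop <= N/2) so every sample is covered by at
#' least two windows and the overlap-add weights never vanish.
#'
#' @param cspec A `"complex_spectrogram"` (from [compute_stft()] or a mask
#'   operation).
#' @return A [waveform()].
#' @export
#' @examples
#' w <- waveform(sin(2 * pi * 2000 * seq(0, 0.5, length.out = 12000)), 24000)
#' y <- reconstruct(compute_stft(w))
#' length(y$samples)
reconstruct <- function(cspec) {
  stopifnot(inherits(cspec, "complex_spectrogram"))
  p <- cspec$params
  N <- p$window_length
  hop <- p$hop
  if (hop > N / 2) {
    stop(sprintf("overlap-add reconstruction requires overlap >= 0.5: window %d with overlap %.2f gives hop %d > %d",
                 N, p$overlap, hop, N %/% 2), call. = FALSE)
  }
  nf <- ncol(cspec$values)
  half <- cspec$values
  # conjugate-symmetric extension; Nyquist bin (not stored) set to zero
  full <- matrix(0 + 0i, N, nf)
  full[seq_len(N %/% 2), ] <- half
  if (N %/% 2 > 1) {
    full[seq(N, N %/% 2 + 2), ] <- Conj(half[seq(2, N %/% 2), , drop = FALSE])
  }
  frames <- Re(stats::mvfft(full, inverse = TRUE)) / N
  w <- stft_window(p)
  frames <- frames * w
  L <- (nf - 1L) * hop + N
  y <- numeric(L)
  den <- numeric(L)
  w2 <- w * w
  for (i in seq_len(nf)) {
    idx <- ((i - 1L) * hop + 1L):((i - 1L) * hop + N)
    y[idx] <- y[idx] + frames[, i]
    den[idx] <- den[idx] + w2
  }
  ok <- den > .Machine$double.eps
  y[ok] <- y[ok] / den[ok]
  y[!ok] <- 0
  waveform(y, cspec$sample_rate)
}
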