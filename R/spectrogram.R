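#' STFT analysis parameters
#'
#' The conventions are fixed so that a 15 s clip at 24 kHz with the default
#' 256-point window and 75% overlap yields a 128 x 5622 spectrogram:
#' windows start at multiples of the hop with no centring or padding, the
#' trailing partial window is discarded, and the frequency axis keeps bins
#' 0 ... N/2 - 1 (DC included, Nyquist excluded).
#'
#' @param window_length FFT window length N in samples (even, >= 4;
#'   default 256). Powers of two are fastest.
#' @param overlap Fractional overlap between consecutive windows in \[0, 1)
#'   (default 0.75). The hop is `round(N * (1 - overlap))` and must be >= 1.
#' @param window_shape Taper name: `"hanning"` (default) or `"hamming"`.
#'   The periodic (DFT-even) form is used, which sums to a constant at
#'   75% overlap and permits clean overlap-add inversion.
#' @return An object of class `"stft_params"` with fields `window_length`,
#'   `overlap`, `window_shape` and the derived `hop`.
#' @export
stft_params <- function(window_length = 256, overlap = 0.75,
                        window_shape = "hanning") {
  if (!is.numeric(window_length) || length(window_length) != 1 ||
      window_length < 4 || window_length != as.integer(window_length) ||
      window_length %% 2 != 0) {
    stop("`window_length` must be an even integer >= 4", call. = FALSE)
  }
  if (!is.numeric(overlap) || length(overlap) != 1 ||
      overlap < 0 || overlap >= 1) {
    stop("`overlap` must lie in [0, 1)", call. = FALSE)
  }
  window_shape <- match.arg(window_shape, c("hanning", "hamming"))
  hop <- as.integer(round(window_length * (1 - overlap)))
  if (hop < 1) stop("hop = round(N * (1 - overlap)) must be >= 1",
                    call. = FALSE)
  structure(list(window_length = as.integer(window_length),
                 overlap = overlap, window_shape = window_shape,
                 hop = hop),
            class = "stft_params")
}

# periodic taper of length n
stft_window <- function(params) {
  n <- params$window_length
  k <- 0:(n - 1)
  switch(params$window_shape,
         hanning = 0.5 - 0.5 * cos(2 * pi * k / n),
         hamming = 0.54 - 0.46 * cos(2 * pi * k / n))
}

#' Number of STFT frames for a signal length
#'
#' Closed form `floor((L - N) / hop) + 1`: one frame per window start
#' `i * hop` with `i * hop + N <= L`. The trailing partial window is
#' discarded, never padded.
#'
#' @param n_samples Signal length L in samples.
#' @param params An [stft_params()] object.
#' @return Integer frame count (0 when `n_samples < window_length`).
#' @export
n_stft_frames <- function(n_samples, params = stft_params()) {
  stopifnot(inherits(params, "stft_params"))
  if (n_samples < params$window_length) return(0L)
  as.integer((n_samples - params$window_length) %/% params$hop + 1L)
}

#' Compute the complex STFT of a waveform
#'
#' Applies the taper to successive windows starting at samples
#' `0, hop, 2*hop, ...` and takes the FFT of each; only the first N/2
#' frequency bins are kept (DC included, Nyquist excluded). Cell `(k, i)`
#' (1-based row k+1, column i+1) has centre frequency `k * sample_rate / N`
#' Hz and centre time `(i * hop + N/2) / sample_rate` seconds.
#'
#' @param waveform A [waveform()] of at least `window_length` samples.
#' @param params An [stft_params()] object.
#' @return An object of class `"complex_spectrogram"`: a list with `values`
#'   (complex matrix, `window_length / 2` rows x frames columns),
#'   `sample_rate` and `params`.
#' @export
#' @examples
#' w <- waveform(sin(2 * pi * 2000 * seq(0, 1, length.out = 24000)), 24000)
#' s <- compute_stft(w)
#' dim(s$values)
compute_stft <- function(waveform, params = stft_params()) {
  stopifnot(inherits(waveform, "waveform"), inherits(params, "stft_params"))
  N <- params$window_length
  L <- length(waveform$samples)
  if (L < N) {
    stop(sprintf("input has %d samples but at least one full window of %d is required",
                 L, N), call. = FALSE)
  }
  hop <- params$hop
  nf <- n_stft_frames(L, params)
  w <- stft_window(params)
  starts <- (seq_len(nf) - 1L) * hop
  # frames as columns of an N x nf matrix, tapered, then batch FFT
  idx <- outer(seq_len(N), starts, `+`)
  frames <- matrix(waveform$samples[idx], nrow = N) * w
  S <- stats::mvfft(frames)[seq_len(N %/% 2), , drop = FALSE]
  structure(list(values = S, sample_rate = waveform$sample_rate,
                 params = params),
            class = "complex_spectrogram")
}

#' @export
print.complex_spectrogram <- function(x, ...) {
  cat(sprintf("<complex spectrogram> %d bins x %d frames @ %d Hz (N=%d, overlap=%.2f)\n",
              nrow(x$values), ncol(x$values), x$sample_rate,
              x$params$window_length, x$params$overlap))
  invisible(x)
}

# cell centre times (s) and frequencies (kHz) for a spectrogram
spectrogram_centres <- function(cspec) {
  N <- cspec$params$window_length
  hop <- cspec$params$hop
  nf <- ncol(cspec$values)
  list(
    time_s = ((seq_len(nf) - 1L) * hop + N / 2) / cspec$sample_rate,
    freq_khz = (seq_len(nrow(cspec$values)) - 1L) *
      cspec$sample_rate / N / 1000
  )
}

#' Convert a complex spectrogram to a dB display spectrogram
#'
#' Takes the modulus and scales to decibels relative to the maximum cell:
#' `20 * log10(|S| / max|S|) + contrast`, clamped to
#' `[-dynamic_range, 0]`. The maximum cell therefore sits at exactly 0 dB
#' and the result is invariant to a positive rescaling of the input audio.
#'
#' @param cspec A [compute_stft()] result.
#' @param dynamic_range Display floor in dB below the maximum (> 0;
#'   default 60).
#' @param contrast Additive dB offset applied before clamping (default 0);
#'   positive values brighten quiet cells.
#' @return An object of class `"db_spectrogram"`: `values` (real matrix of
#'   dB values in `[-dynamic_range, 0]`), `sample_rate`, `params`,
#'   `time_extent` (seconds) and `freq_extent` (kHz).
#' @export
to_db <- function(cspec, dynamic_range = 60, contrast = 0) {
  stopifnot(inherits(cspec, "complex_spectrogram"))
  if (!is.numeric(dynamic_range) || length(dynamic_range) != 1 ||
      !is.finite(dynamic_range) || dynamic_range <= 0) {
    stop("`dynamic_range` must be a positive number of dB", call. = FALSE)
  }
  mag <- Mod(cspec$values)
  peak <- max(mag)
  if (peak == 0) {
    db <- matrix(-dynamic_range, nrow(mag), ncol(mag))
  } else {
    db <- 20 * log10(mag / peak) + contrast
    db <- pmin(pmax(db, -dynamic_range), 0)
  }
  N <- cspec$params$window_length
  nf <- ncol(cspec$values)
  structure(list(
    values = db, sample_rate = cspec$sample_rate, params = cspec$params,
    time_extent = c(0, ((nf - 1L) * cspec$params$hop + N) /
                      cspec$sample_rate),
    freq_extent = c(0, cspec$sample_rate / 2 / 1000)
  ), class = "db_spectrogram")
}

#' @export
print.db_spectrogram <- function(x, ...) {
  cat(sprintf("<dB spectrogram> %d x %d, time %.2f-%.2f s, freq %.2f-%.2f kHz\n",
              nrow(x$values), ncol(x$values),
              x$time_extent[1], x$time_extent[2],
              x$freq_extent[1], x$freq_extent[2]))
  invisible(x)
}

#' Zoom a dB spectrogram to a time-frequency box
#'
#' Returns the sub-matrix of cells whose centres fall inside the (closed)
#' box; dB values are not re-normalized, so contrast is comparable before
#' and after zooming. Extents are updated to the intersection of the box
#' with the original extent.
#'
#' @param dbspec A [to_db()] result.
#' @param box A [bounding_box()] in seconds x kHz.
#' @return A zoomed `"db_spectrogram"`.
#' @export
zoom <- function(dbspec, box) {
  stopifnot(inherits(dbspec, "db_spectrogram"), inherits(box, "bounding_box"))
  N <- dbspec$params$window_length
  hop <- dbspec$params$hop
  nf <- ncol(dbspec$values)
  time_s <- ((seq_len(nf) - 1L) * hop + N / 2) / dbspec$sample_rate
  freq_khz <- (seq_len(nrow(dbspec$values)) - 1L) * dbspec$sample_rate / N / 1000
  cols <- which(time_s >= box$t_start & time_s <= box$t_end)
  rows <- which(freq_khz >= box$f_start & freq_khz <= box$f_end)
  if (length(cols) == 0 || length(rows) == 0) {
    stop("zoom box does not contain any spectrogram cell centres",
         call. = FALSE)
  }
  dbspec$values <- dbspec$values[rows, cols, drop = FALSE]
  dbspec$time_extent <- c(max(box$t_start, dbspec$time_extent[1]),
                          min(box$t_end, dbspec$time_extent[2]))
  dbspec$freq_extent <- c(max(box$f_start, dbspec$freq_extent[1]),
                          min(box$f_end, dbspec$freq_extent[2]))
  dbspec
}
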