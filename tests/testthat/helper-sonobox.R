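# Shared fixtures, built in code at test time.

# pure tone as a waveform
tone_wave <- function(freq_hz, seconds = 1, sr = 24000, amp = 0.8) {
  waveform(amp * sin(2 * pi * freq_hz * (0:(round(seconds * sr) - 1)) / sr),
           sr)
}

# band-limited random signal: tapered tone/chirp mixture (content kept well
# below Nyquist so the discarded Nyquist bin carries negligible energy)
random_bandlimited_signal <- function(seconds = 0.35, sr = 24000,
                                      n_events = 5, max_khz = 7) {
  events <- lapply(seq_len(n_events), function(i) {
    kind <- sample(c("tone", "chirp"), 1)
    t0 <- runif(1, 0, seconds * 0.5)
    t1 <- runif(1, t0 + 0.05, seconds)
    f0 <- runif(1, 0.3, max_khz)
    f1 <- if (kind == "chirp") runif(1, 0.3, max_khz) else f0
    synthetic_event(kind, t0, t1, f0, f1, amplitude = runif(1, 0.2, 0.8))
  })
  w <- make_signal(events, duration_seconds = seconds, sample_rate = sr,
                   noise_floor = 0, seed = sample.int(1e6, 1))
  # keep the mixture inside the [-1, 1] audio range
  waveform(w$samples / max(abs(w$samples), 1) * 0.9, sr)
}

# small in-memory annotation set
make_test_set <- function(rows) {
  set <- annotation_set()
  for (r in rows) {
    set <- add_annotation(set, create_annotation(
      bounding_box(r$t0, r$t1, r$f0, r$f1), class_label = r$class,
      file_name = r$file, confidence = r$conf %||% 100,
      labeller = r$labeller %||% "tester",
      clip_duration = 15, nyquist = 12))
  }
  set
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# signal energy
energy <- function(x) sum(x^2)
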