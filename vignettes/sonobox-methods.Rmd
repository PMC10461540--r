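---
title: "Spectrogram conventions, time-frequency filtering and annotation handling in sonobox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectrogram conventions, time-frequency filtering and annotation handling in sonobox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonobox)
```

## The problem

Passive acoustic monitoring projects collect thousands of hours of field
audio from autonomous recorders. Annotating that audio for downstream
machine learning means drawing *bounding boxes* on spectrograms — rectangles
in time (seconds) by frequency (kHz) around individual vocalisations — and
attaching a class, a confidence and free-text context to each box. sonobox
implements the headless core of such a workflow: spectrogram computation
under fixed conventions, filtered-audio reconstruction so a labeller can
listen to exactly the selected region, the label CSV schema, per-site
species lists with BTO (British Trust for Ornithology) letter codes,
recorder metadata, and deterministic rendering.

## STFT conventions

The short-time Fourier transform uses a periodic Hann taper of
`window_length` samples (default N = 256), windows starting at samples
`0, hop, 2·hop, …` with `hop = round(N·(1 − overlap))` (default overlap
0.75, hop 64). Three conventions are fixed deliberately:

* **No centring or padding.** The first window starts at sample 0 and the
  trailing partial window is discarded, so the frame count is
  `floor((L − N)/hop) + 1`. For a 15 s clip at 24 kHz this yields exactly
  5622 frames.
* **Bins 0 … N/2 − 1.** DC is kept, the Nyquist bin is excluded, giving
  128 rows at N = 256. Together with the 5622 frames this is the package's
  shape contract (719,616 cells for the default clip).
* **Cell centres.** Cell (k, i) is centred at frequency `k·sr/N` Hz and
  time `(i·hop + N/2)/sr` s. All geometric operations — zooming, box
  masking, band filtering — classify a cell by whether its *centre* falls
  in the closed query rectangle. Centre membership is symmetric and
  orientation-free; the alternative (any-overlap) makes masks grow by half
  a cell per edge and is harder to reason about in tests.

The display transform is `20·log10(|S|/max|S|) + contrast`, clamped to
`[−dynamic_range, 0]` (default dynamic range 60 dB). The maximum cell sits
at exactly 0 dB, so display is invariant to input gain. *Contrast* is
implemented as an additive dB offset before clamping: it brightens quiet
structure at the cost of saturating loud cells, which matches how such a
control is used while hunting faint vocalisations. An all-zero spectrogram
maps to a uniform floor rather than dividing by zero.

## Masking and reconstruction

Selection filtering keeps the *complex* spectrogram in the back end:

* **zero mode** multiplies cells outside the selection by `epsilon`
  (default exactly 0);
* **attenuate mode** divides outside magnitudes by `attenuation_factor`
  (default 100), the gentler option when fully zeroed audio sounds
  unnatural.

Both act by scaling the complex values, so phase is preserved wherever
magnitude survives. Masking can therefore never increase energy, zero-mode
masking is idempotent, and attenuate-mode masking compounds as the factor
squared.

Reconstruction is a weighted overlap-add inverse STFT: each half-spectrum
column is conjugate-symmetrically extended (the absent Nyquist bin is taken
as zero), inverse-FFT'd, multiplied by the analysis window used again as
synthesis window, overlap-added, and normalised by the summed squared
window. With overlap ≥ 0.5 the summed squared Hann window never vanishes on
the interior and the round trip is exact up to the discarded Nyquist bin;
the function refuses hops larger than N/2. Output length is
`(frames − 1)·hop + N`; callers needing the original length pad or truncate
explicitly, which keeps the operator linear and honest about the samples it
cannot reconstruct.

**Precision caveat.** Because the 128-row contract discards the Nyquist
bin, round-trip accuracy depends on how much signal energy sits at the top
of the band. For unit-range mixtures of tapered tones and chirps kept at or
below 7 kHz (of a 12 kHz Nyquist) the interior round-trip error stays below
10⁻⁶; broadband white noise, which has substantial Nyquist-bin energy,
round-trips only to about 10⁻². The package's property tests use the former
— the generator's events emulate band-limited vocalisations, and field
recorders apply anti-alias filtering with similar headroom — so a passing
round-trip test says nothing about signals with appreciable energy in the
top FFT bin.

## Row-wise noise reduction

The noise reducer is median-magnitude spectral subtraction: for each
frequency row, the median magnitude over frames estimates that band's
stationary noise level and is subtracted from every cell (floored at zero,
phase preserved). The median is chosen over the mean for robustness: a
vocalisation present in fewer than half the frames of its rows leaves the
median — and hence itself — nearly untouched. For stationary Gaussian noise
the magnitudes are Rayleigh; with median `σ√(2 ln 2)` the expected residual
mean magnitude is `erfc(√(ln 2)) ≈ 0.24` of the original, i.e. roughly a 76%
reduction, which is what the tests assert (measured 76.2% on the synthetic
chirp-plus-noise mixture, versus under 2% reduction on the chirp's own
trajectory cells).

## Annotation schema

Labels are plain CSV with seven required columns (`date_time`, `file_name`,
`start_time`, `end_time`, `start_freq`, `end_freq`, `class_label`) and four
optional ones (`confidence`, defaulting to 100; `labeller`; `call_type`;
`notes`). Times are clip-relative seconds and frequencies kHz; recording-
relative times are recoverable through the filename's `_start_MM_SS`
offset. `date_time` is the label's creation stamp in ISO 8601 with a
numeric zone offset (`yyyy-mm-ddTHH:MM:SSZZZZ`); parsed offsets are kept as
text and never silently converted, since a labelling campaign can span
annotators in different zones. Confidence is an integer percent 0–100 — a
slider in the interactive tools this schema comes from, with no finer scale
defined. Input CSVs may carry a UTF-8 byte-order mark (spreadsheet exports
often do); output is BOM-less UTF-8. Files are written to
`labels/labels_<username>.csv`, or `labels/labels_tmp.csv` when no username
is configured. Edits are atomic: a failed validation leaves the set exactly
as it was, and `date_time`/`file_name` are immutable provenance.

## Species lists, classes and metadata

`species_list.csv` holds one column per site, headed by the site name;
columns may be ragged, and each site's list is deduplicated and sorted
alphabetically at load. Merging an uploaded list appends only new site
columns, so merges are idempotent and never alter existing sites. The
session class list orders core site species (green border), miscellaneous
categories (orange; defaults `Human`, `Insect`, `Weather noise`, `Unknown`,
configurable and global rather than per-site), then manually added classes
(blue); a label whose class is in none of these renders grey. Class-name
matching is case-sensitive exact match throughout — silent aliasing between
"wren" and "Wren" would corrupt downstream counts. BTO code application
only changes `display_code`, never `name`, and is idempotent.
`location_list.csv` requires only `recorder_name`; every other field may be
blank and unknown columns are carried verbatim.

## Rendering

Images are composited directly into an RGB array and written with
`png::writePNG`: no graphics device, so output is byte-deterministic, the
pixel dimensions are exactly as requested, and the base raster is
independent of the overlay layers (adding an annotation can only touch
pixels of its own box and label). The dB raster is nearest-neighbour
resampled, mapped through a 256-step `grDevices::hcl.colors()` palette
(default `"viridis"`) with 0 dB at the palette top and frequency increasing
upward. Label text uses a built-in 5×7 bitmap font (uppercase and digits;
lowercase folds to uppercase), drawn at the box's upper edge.

## The synthetic-data generator

`make_signal()` sums tapered sinusoids, linear chirps and band-limited
noise bursts at stated time-frequency boxes over an optional Gaussian noise
floor, deterministically per seed. Events carry 10 ms raised-cosine edges
so their energy stays inside the stated box instead of splattering across
the test oracles. `make_demo_project()` assembles a full project folder —
three 15 s, 24 kHz WAV clips named for real Irish wind-farm recorders
(RAHORA, CLOOSHVALLEY, TEEVURCHER), species/location/BTO CSVs and a
ground-truth label file describing the embedded events. The latitude/
longitude values and the 6-row BTO table are synthetic stand-ins; the
generator emulates the *formats and geometry* of field data, not its
acoustics: no reverberation, no overlapping vocalisation mixtures, no
recorder self-noise spectrum, no amplitude modulation. Tests passing on
these fixtures validate the pipeline's bookkeeping and signal-processing
contracts, not species recognisability in real soundscapes.

## Numerical and design choices

* Multi-channel WAVs are mono-mixed by channel averaging; recorder fleets
  in this workflow are mono.
* Gain (`10^(dB/20)`) never clips in memory; samples are clamped to
  [−1, 1] only when written, with a warning.
* Normalisation is peak normalisation to 1.0; an all-zero waveform is
  returned unchanged with a warning.
* The recorder token is everything before the first `_` that is followed by
  the 8-digit date; `_start_` offsets must be below one hour because
  `MM_SS` cannot encode more.
* Attenuation acts on magnitude, not power.
* Windows: periodic Hann default; Hamming available. Window/overlap pairs
  violating the overlap-add condition are rejected at reconstruction, not
  at analysis, since analysis alone is valid for any hop.
* Problem sizes in the test-suite: single 15 s clips for the dimension
  contract, 0.25–1 s clips elsewhere, 20-signal round-trip batches and
  200-configuration frame-count sweeps — small enough to run in seconds
  while exercising every contract at full default parameters.

## Known limitations

* No resampling, compressed-audio reading, or ultrasonic (bat) pipeline.
* Zero-mode filtering produces audible ringing on strong edges; that is
  inherent to hard spectrogram masking and is why attenuate mode exists.
* The renderer's font covers A–Z, digits and basic punctuation only.
* Concurrent multi-user label merging is out of scope; one CSV per
  labeller.
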