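Package: sonobox
Title: Spectrogram Computation, Time-Frequency Filtering and Bounding-Box
    Annotation for Bioacoustic Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A headless toolkit for annotating passive acoustic monitoring
    recordings with time-frequency bounding boxes. Computes short-time
    Fourier transform (STFT) spectrograms under fixed windowing conventions,
    produces selection-filtered audio by complex-spectrogram masking and
    inverse-STFT overlap-add reconstruction (box, band-pass and row-wise
    median noise-reduction masks), and manages the annotation CSV schema,
    per-site species lists, British Trust for Ornithology (BTO) species-code
    lookup and recorder site metadata used by field annotation projects.
    Includes a synthetic-audio fixture generator with known time-frequency
    ground truth, a deterministic PNG spectrogram renderer with layered
    annotation overlays, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
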