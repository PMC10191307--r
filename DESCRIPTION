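Package: somnseq
Title: Multi-Class Sleep Staging from Wrist-Wearable Activity and Coarse Heart Rate
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Three- and four-class sleep staging from 30-second-epoch activity
    counts and two coarse cardiac measures (per-epoch instantaneous-heart-rate
    mean and standard deviation), the kind of inputs a consumer wrist wearable
    provides. The classifier is a sequence-to-sequence network: a stack of
    one-dimensional convolutions feeds an attention-guided LSTM
    encoder-decoder that labels every epoch of a sliding 12-epoch window, and
    overlapping window predictions are combined by mode voting. Training
    supports inverse-frequency-weighted cross-entropy and a real-world
    weighting that also penalises false positives of under-represented stages
    such as deep (N3) sleep. The package includes the preprocessing rules for
    R-peak trains (artifact interval correction, two-standard-deviation
    outlier rejection), 60-second activity upsampling, accelerometry-to-counts
    conversion, cross-correlation channel alignment, subject-wise data
    splitting with validation-based model selection and fine-tuning, a
    synthetic cohort generator (Markov hypnograms with stage-conditional
    emissions and R-peak trains), classifier metrics (including macro
    one-vs-rest Matthews correlation), and clinical sleep metrics (sleep
    efficiency, onset latency, fragmentation, stage times, and a sleep
    transition index).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    yaml,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
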