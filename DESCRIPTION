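Package: hgtune
Title: Tuning Maps and Speech Encoding Analysis for Human Auditory Cortex Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of speech encoding in intracranial recordings
    from Heschl's gyrus: cochlear-model auditory spectrograms, high-gamma
    envelope extraction, spectrotemporal receptive field (STRF) estimation by
    regularized reverse correlation with cross-validated electrode inclusion,
    extraction of per-site tuning attributes (best frequency, response
    latency, best temporal modulation, speaker invariance, speech
    sensitivity), phoneme-aligned decoding with a regularized least-squares
    classifier, and joint spatial gradient analysis (PCA and CCA) over
    electrode feature maps. Includes a ground-truth synthetic cohort
    generator so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    signal,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
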