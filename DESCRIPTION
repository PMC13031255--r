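Package: compslide
Title: Analysis of Continuous Real-Time Speech-Comprehension Slider Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for behavioral experiments that record speech comprehension
    in real time with a continuous slider device sampled at 250 Hz as 8-bit
    positions. Parses timestamp-paired device logs and corrects clock drift,
    resamples and normalizes traces, and computes trial-level slider summaries
    (median score, initial-movement cropping, pentile profiles, movement-based
    attention checks). Scores written summaries against heard segments with
    three word-embedding similarity measures, fits and compares linear and
    sigmoidal comprehension-versus-speech-rate models under rate-stratified
    cross-validation, and estimates temporal response functions (time-lagged
    ridge regression) that predict the slider signal from stimulus annotation
    impulses, including per-participant response-delay kernels and
    surprisal-feature ablation. A synthetic-data generator emulates devices,
    sessions, word events, embeddings and summaries with known ground truth so
    every stage is testable without hardware or downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
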