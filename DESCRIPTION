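Package: deleeg
Title: Quantitative EEG Delirium Screening with Autoregressive Spectra and
    Renormalized Partial Directed Coherence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for quantitative electroencephalography
    (QEEG) screening of delirium in intensive-care patients. Implements
    high-order Burg autoregressive spectral estimation with split-band
    relative power normalization, the slow-to-fast frequency power ratio
    (SFPR), renormalized partial directed coherence (rPDC) computed from
    least-squares vector autoregressive fits with a chi-square chance level
    and a confidence-interval counting rule for group differences over
    frequency ranges, balanced two-way ANOVA with Bonferroni post-tests,
    exact Mann-Whitney tests, a minimal EDF/BDF reader and writer with
    artifact-aware epoch selection, and a seeded synthetic EEG cohort
    generator with known band-power profiles and directed coupling for
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
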