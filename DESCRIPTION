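Package: ecoglex
Title: Word-Complexity Correlates in Intracranial Recordings of Spontaneous Speech
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating word-complexity measures of spontaneously
    spoken words (syllable count, consonant-to-vowel ratio, an
    ease-of-articulation index, and lemma frequency) to word-aligned spectral
    power in multichannel electrocorticographic (ECoG) recordings. Implements
    common-average referencing, multitaper spectrograms with Slepian tapers,
    per-trial baseline-relative spectral magnitudes on a natural-log scale,
    time-frequency-resolved Pearson correlation maps ("neurocorrelation")
    with Bonferroni and threshold-ladder testing, collinearity assessment and
    confound residualization by linear regression, and matching of effect
    clusters before and after residualization. Ships a seeded synthetic-data
    generator (Zipfian lexicon, pause-segmented discourse, 1/f background
    with parameter-coupled gamma bursts) so the whole pipeline can be
    exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
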