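Package: ToneContours
Title: Synthesis and Recognition of Mandarin Tone F0 Contours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying lexical tone perception from syllable-sized
    fundamental-frequency (f0) contours. Provides a quantitative
    target-approximation (qTA) forward model to synthesize Mandarin-like
    disyllabic tone corpora with speaker pitch differences and
    cross-syllable f0 carryover; feature representations ranging from the
    raw 30-point contour to two- and five-level pitch codes,
    parabola/broken-line stylization cues, and qTA parameters recovered by
    analysis-by-synthesis; SVM and self-organizing-map tone recognizers;
    and an experiment driver that compares the recognition accuracy and
    testing-phase time complexity of the competing schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    e1071,
    yaml,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
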