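Package: caevents
Title: Calcium Imaging Event Detection, Spatial Patterns, and Group Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for in vivo calcium-imaging recordings of
    invertebrate neuropils: percent delta-F/F trace processing with a
    zero-phase band-pass filter and percentile baseline, rule-based
    detection of spontaneous calcium transients, quantification of
    stimulus-evoked responses by window summation, spatial activity-pattern
    extraction and K-means clustering, and the mixed-design ANOVA / post hoc
    battery used for group comparisons. A synthetic-data generator produces
    traces, movies and whole cohorts with known ground truth so every stage
    of the analysis can be verified end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    tiff,
    png,
    jsonlite,
    yaml,
    pracma,
    cluster
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
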