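Package: enhancerlift
Title: Functional Motif Discovery in Enhancers from Sequence Classifiers
    and Per-Nucleotide Importance Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for identifying candidate functional
    transcription-factor binding motifs in enhancer sequences. Builds a
    labelled enhancer dataset from peak intervals and histone-mark tag
    counts (tag-count filtering, sex-chromosome removal, GC-matched
    negatives, chromosome-holdout splits), trains a small convolutional
    sequence classifier, derives per-nucleotide importance scores with a
    DeepLIFT-style rescale rule against a uniform background and
    reverse-complement absolute-maximum strand aggregation, calibrates
    position-weight-matrix score cutoffs to an empirical per-window
    false-positive rate, and calls functional motifs as PWM matches whose
    footprint intersects the per-sequence top-importance positions. A
    synthetic-data module generates genomes, peaks, tag counts and planted
    motif instances with known ground truth so every stage is testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
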