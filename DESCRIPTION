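Package: rotaskip
Title: Exon Skipping Prediction from RNA-Seq and Genome Sequence with
    Rotation Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects cassette-exon skipping events from two-tissue RNA-Seq
    evidence combined with genome sequence context. Extracts per-event read
    counts (exon body, introns, inclusion and exclusion junctions, gene),
    effective-length-normalised features, percent-spliced-in and tissue
    divergence features, and sequence structure/nucleotide-composition
    features; classifies events with a from-scratch Rotation Forest
    (per-subset PCA rotations over random feature partitions, unpruned
    CART base trees, maximum-average-confidence voting). Includes a
    two-tissue cassette-exon read simulator, consensus labelling and
    stratified-split helpers, ROC/AUC evaluation, and a command-line
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rpart,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
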