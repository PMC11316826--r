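Package: dmcbench
Title: Benchmarking Metagenomic Taxonomic Classifiers Against Defined Mock Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates the output of metagenomic taxonomic classifiers against
    defined mock communities (DMCs) with known composition. Parses kraken-style
    reports, mpa-style clade profiles and a generic tabular profile dialect;
    synchronizes taxon identifiers against an NCBI-style taxonomy dump
    (nodes/names/merged/delnodes); projects classifications to genus and
    species rank; and computes detection precision, recall and F1, the L1
    distance between relative abundance vectors, precision-recall curves under
    relative-abundance threshold filtering, and the area under the
    precision-recall curve (AUPRC) by the trapezoid rule. Includes nanopore
    read-set quality statistics (N50, length quartiles, Q20/Q30), length and
    mean-quality read filtering, seeded subsampling to a base target,
    read-length-distribution matching, per-classifier aggregation across
    samples, and a synthetic-data generator (mock ground truths, noisy
    classifier profiles, mini taxonomy dumps, FASTQ fixtures) so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
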