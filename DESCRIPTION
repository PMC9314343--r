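Package: chromarch
Title: Chromatin Architecture Analysis: TADs, Loops, Compartments and
    Regulatory Enrichment from Hi-C Contact Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing three-dimensional chromatin architecture
    from binned Hi-C contact matrices and matched regulatory data:
    insulation-score and directionality-index TAD boundary detection,
    focal-enrichment loop calling with a donut local background,
    per-sample domain scoring with custom size-factor normalisation and
    threshold-aware differential testing, A/B compartment eigenvectors,
    super-enhancer stitching with a tangential-diagonal cutoff, position
    weight matrix scanning with CTCF anchor orientation, motif
    co-association networks, ranked set enrichment (ES/NES with a
    permutation null), and exact small-sample tests. Includes a synthetic
    data generator that plants TADs, loops, compartments, anchor-resident
    peaks, motifs and differential expression with recorded ground truth,
    so every caller can be benchmarked by recovery on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
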