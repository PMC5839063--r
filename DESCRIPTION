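Package: argboxr
Title: Information-Theoretic Modelling of ArgR Operator (ARG Box) Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds Schneider-style individual-information models of the
    ArgR repressor operator (the "ARG box") of Streptomyces coelicolor from
    curated 20-nt binding-site alignments, scores sequences in bits (Ri),
    computes the model conservation (Rsequence) with an exact small-sample
    entropy correction, discovers palindromic motifs in probe sets by EM
    (ZOOPS and ANR occurrence models, optionally discriminative), scans
    genome-scale sequences with exact dynamic-programming p-values and the
    dual filter used for operator prediction (p-value and Ri thresholds),
    classifies single and tandem binding-site architectures, associates
    predicted sites with downstream genes, and generates fully synthetic
    high-GC benchmark genomes and probe sets with planted sites for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
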