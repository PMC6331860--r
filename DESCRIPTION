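Package: sqbvs
Title: Quantum-Inspired Similarity Searching for Ligand-Based Virtual
    Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Similarity searching over sparse count fingerprints (ECFC-style
    fragment-count vectors) with the Standard Quantum-Based (SQB) similarity
    measure: compounds are embedded as complex-valued vectors in a Hilbert
    space using Okapi-style fragment weighting (three imaginary-part
    techniques plus a real-valued special case) and scored by the quantum
    projection probability of the reference state onto the compound subspace.
    Includes the continuous Tanimoto coefficient as a benchmark, a full
    screening-evaluation protocol (recall at top 1%/5% cutoffs, per-class
    tables with mean and best-cell summaries), Kendall coefficient of
    concordance with tie correction for method ranking, and a synthetic
    benchmark generator with calibratable intra-class diversity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
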