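Package: daccspot
Title: Recombination Hot/Cold Spot Classification from Dinucleotide
    Auto-Cross Covariance Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Encodes DNA sequences into dinucleotide-based auto-cross
    covariance (DACC) feature vectors built from fifteen physicochemical
    dinucleotide properties, optionally reduces them by principal component
    analysis under a cumulative-variance criterion, and trains and evaluates
    an RBF-kernel support vector machine that separates meiotic
    recombination hotspots from coldspots. Includes jackknife and stratified
    k-fold evaluation protocols with sensitivity, specificity, accuracy and
    Matthews correlation reporting, a discriminative feature-weight readout
    for interpretation, a calibrated synthetic sequence generator for
    end-to-end testing without external data, and a command-line interface
    covering the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    kernlab,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
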