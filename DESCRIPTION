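Package: pfrnb
Title: Significance, Fragility, and Robustness Triplets for Two-Arm Binary Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes the p-fr-nb evidence triplet for two-arm clinical trials
    with binary outcomes: a two-sided p-value (Fisher's exact test or Pearson's
    chi-square, chosen by a context-dependent rule), the modified-arm fragility
    quotient (MFQ, the fragility index normalised by the size of the toggled
    arm), and the risk quotient (RQ, a 0-1 measure of geometric distance from
    therapeutic neutrality). Trials are classified into evidence patterns
    (concordant-positive, significant-fragile-weak, concordant-null and
    residual categories). Includes a Monte Carlo trial simulator over factorial
    design grids to establish null and non-null pattern expectations,
    prevalence summaries with Wilson score intervals, exact binomial
    enrichment tests, CSV input/output for trial collections, and a synthetic
    fixture generator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
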