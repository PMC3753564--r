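Package: snvcompare
Title: Comparative Analysis of Somatic SNV Callers on Matched Cancer-Normal Pileups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale re-implementations of four matched cancer-normal
    somatic single-nucleotide-variant calling models (a heuristic
    genotype/Fisher caller, a joint-genotype Bayesian caller, a
    beta-binomial joint mixture trained by MAP expectation-maximization,
    and a marginalized allele-frequency caller sensitive to low-fraction
    variants), together with a post-calling filter suite (strand bias,
    base and mapping quality, nearby SNV, spanning-deletion and
    adjacent-indel rules), caller concordance and characterization
    statistics, and a synthetic paired-pileup generator with ground truth,
    including a normal-normal split null for false-positive auditing.
    Every stage runs on simulated data or on two-sample text pileups.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, tools
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
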