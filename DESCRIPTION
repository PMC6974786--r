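Package: accliff
Title: Analog-Series-Based Activity Cliff Detection with Target-Set-Dependent
    Potency Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies activity cliffs in compound potency data by systematic
    retrosynthetic (RECAP-rule) fragmentation of exocyclic single bonds,
    extraction of analog series sharing a hydrogen-generalized core, and a
    target-set-dependent potency-difference threshold (mean plus two standard
    deviations of the analog-pair delta-pKi distribution). Detects single- and
    multi-site cliffs, provides a matched-molecular-pair (MMP/RMMP) detection
    mode, and decomposes dual-site cliffs by searching for single-site analogs
    carrying the individual substitutions. Includes a deterministic synthetic
    fixture generator with planted potency structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
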