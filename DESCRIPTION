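Package: ddtsim
Title: Simulation and Quantification of DNA Damage Tolerance Pathway Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the fate of a single replication-blocking DNA lesion
    integrated into the Escherichia coli chromosome. Provides a stochastic
    per-integration model of damage-tolerance outcomes (homology-directed gap
    repair, translesion synthesis, damaged-chromatid loss, death), synthetic
    heteroduplex marker constructs with in-silico PCR and restriction-digest
    decoding of colony genotypes, and the quantification and inference
    procedures used with such assays: internal-standard normalization,
    marker-conversion correction, Poisson zero-class correction for clustered
    UV lesions, and estimation of the endogenous opposite-strand lesion
    burden from relative survival.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
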