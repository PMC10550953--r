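Package: haplocna
Title: Haplotype-Specific Somatic Copy-Number Evolution Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of haplotype-specific somatic
    copy-number alterations (SCNAs) in multi-sample tumor cohorts.
    Provides a mechanistic clone-evolution simulator (breakage-fusion-bridge
    cycles, chromothripsis, uniparental disomy, whole-genome duplication,
    progressive terminal erosion), correction of statistical-phasing switch
    errors from cross-sample allelic imbalance, allele-specific copy-number
    calling with grid-search purity/ploidy estimation, mechanistic SCNA
    classification including sloping copy-number detection, SCNA-breakpoint
    phylogenetics with WGD placement and timing, and per-sample burden
    summaries with group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse,
    phangorn,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
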