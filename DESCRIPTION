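Package: epistree
Title: Tree-Based Detection of SNP-SNP Interactions in the Presence of a
    Polygenic Signal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for studying how rule-based decision trees
    (a C4.5/C5.0-style learner) and logic regression detect epistatic
    SNP-SNP interactions in quantitative traits, alone and on top of a
    polygenic background.  Provides a Hardy-Weinberg genotype generator
    with optional block linkage disequilibrium, PLINK text import/export,
    LD pruning, phenotype simulators for polygenic, two- and three-SNP
    interaction models with a bias/coverage audit, both learners with a
    100-permutation randomisation test, and a replicate-level harness
    that estimates power and type I error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
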