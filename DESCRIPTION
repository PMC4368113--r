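Package: polyParent
Title: Parentage Assignment and Breeding-System Analysis for Polygamous
    Fish Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for reconstructing the breeding system of wild fish
    populations from codominant microsatellite genotypes of candidate
    parents and offspring. Provides GenePop and tabular genotype I/O,
    per-locus diversity statistics (observed and unbiased expected
    heterozygosity, polymorphic information content, Hardy-Weinberg
    tests), multilocus match analysis for duplicate-sample detection
    with probability-of-identity support, exact-enumeration Bayesian
    parentage assignment under a Mendelian transition model with
    genotyping error, mating-network reconstruction with phantom
    (unsampled) partners, reproductive-skew summaries, Poisson
    regression of reproductive success, and estimation of the effective
    number of breeders with percentile-bootstrap confidence intervals.
    A polygynandrous mating-system simulator with full truth tables
    supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'polyParent-package.R'
    'utils.R'
    'AllClasses.R'
    'genotype-table.R'
    'io.R'
    'locus-stats.R'
    'duplicates.R'
    'parentage.R'
    'mating-network.R'
    'nb.R'
    'glm-tests.R'
    'simulate.R'
    'pipeline.R'
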