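Package: germstrata
Title: Timing, Rates and Spectra of Germline De Novo Mutations in
    Multi-Sibling Pedigrees
Version: 0.1.0
Authors@R:
    person("Pedigree", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies germline de novo mutations (DNMs) observed in
    multi-sibling pedigrees into four temporal strata of the germline
    (very early embryonic, early embryonic, peri-primordial-germ-cell and
    late post-PGC) from tissue-level allele fractions, parental mosaicism
    tests, sibling sharing and read-pair phase evidence; estimates
    mutation rates per generation, per year and per cell division under an
    explicit germline cellular demography, including the partial germline
    contribution of mosaic first-cleavage mutations; compares
    seven-category mutation spectra; and reconstructs parental embryonic
    cell lineages from the co-occurrence of shared mutations. A synthetic
    pedigree generator emulates the data structure of deep multi-tissue
    pedigree sequencing so that every stage is testable without external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    Biostrings
Config/testthat/edition: 3
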