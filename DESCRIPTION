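Package: hyperhaploidy
Title: Whole-Chromosome Copy Number, LOH and Double-Hit TP53 Analysis for
    Hyperhaploid Myeloma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers whole-chromosome copy number and loss of heterozygosity
    (LOH) from tumor/normal SNP allele counts, renormalizes ploidy so that
    LOH chromosomes map to copy number one, classifies karyotypes into
    hyperhaploid (24-34 chromosomes) and hyperdiploid (47-57 chromosomes)
    groups, discriminates between three whole-chromosome loss mechanisms by
    the fraction of disomic chromosomes carrying LOH, and calls bi-allelic
    ("double-hit") TP53 inactivation with clonality and event-order
    inference from mutation cancer cell fractions. A synthetic-data module
    simulates karyotype evolution, binomial read counts and spiked somatic
    mutations so the whole pipeline is testable without controlled-access
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
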