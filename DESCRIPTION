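Package: clonarch
Title: Clonal Ordering and Liquid-Biopsy Quantification for Early Lung
    Neoplasia Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multi-region targeted sequencing of early
    lung glandular neoplasms (AAH, AIS, MIA) and paired circulating DNA.
    Implements matched tumour/normal somatic mutation calling from distinct
    read-pair tallies with explicit rule-coded filters, per-gene copy-number
    calls from normalized coverage ratios, containment-based clonal-ancestry
    dendrograms across lesion zones with Newick export, cohort mutation-rate,
    substitution-spectrum, stage-overlap, heterogeneity and progression
    statistics, and Poisson-partition droplet digital PCR quantification of
    mutant circulating DNA including limit-of-detection dilution series.
    A seeded multi-zone clonal-evolution simulator generates ground-truthed
    cohorts so the whole chain is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
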