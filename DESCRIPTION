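Package: nof1omics
Title: Single-Subject Multi-Omic Outlier Analysis for Sex-Chromosome Aneuploidy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterizing a single index individual against a
    reference cohort across methylation, expression and genotyping arrays.
    Implements karyotype inference from X-methylation clustering, XIST
    expression, Y-probe signal, X heterozygosity and B-allele-frequency band
    counting; per-feature singleton z-score outlier tests with
    chromosome-aware comparison groups and Bonferroni correction; adjacent
    probe aggregation into differentially methylated regions with Stouffer
    combination and copy-number overlap screening; LINE-1/Alu repeat-element
    global methylation assessment; X-chromosome-inactivation skewing from
    allelic peak heights; and a fully synthetic multi-omic cohort generator
    so the whole workflow is testable without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
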