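Package: hrdkit
Title: Genomic Scar Scoring and SNP Panel Design for Homologous
    Recombination Deficiency Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting homologous recombination deficiency (HRD)
    from targeted SNP sequencing of tumor/normal pairs. Implements design of
    evenly spaced non-exonic SNP backbone panels from population variant
    tables (minor-allele-frequency, exon-distance, Hardy-Weinberg and GC
    filters, 50-kb window selection ranked by a chosen population's allele
    frequency), simulation of tumors with planted copy-number scar events
    and binomial/Poisson read counts under a purity-ploidy mixture model,
    allele-specific copy-number inference (logR/BAF segmentation and
    exhaustive purity-ploidy grid fitting), the three genomic scar scores
    (loss of heterozygosity, telomeric allelic imbalance, large-scale state
    transitions) with the HRD sum and the clinical cutoff of 42, and
    in-silico validation experiments: purity dilution, depth titration,
    panel subsetting concordance, heterozygosity binning and ROC analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
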