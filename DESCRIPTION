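Package: homeobias
Title: Homoeolog Expression Bias Analysis for Allopolyploid RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies allele-specific and homoeolog-specific expression in
    hybrid and allopolyploid organisms from per-site allele read counts.
    Starting from RNA-seq allele-count tables for parental and hybrid
    libraries, the package identifies genome-diagnostic SNPs from the
    parental libraries, estimates and corrects reference-mapping bias using
    intragenomic heterozygous sites, aggregates corrected per-site counts
    into per-transcript homoeolog fractions, classifies transcripts into
    balanced, biased and monogenomic expression categories with
    ploidy-specific balance windows, tests bias direction and ploidy effects
    with chi-squared tests, and performs hypergeometric term enrichment on
    monogenomic expression groups. A synthetic-data generator with a known
    ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    SummarizedExperiment,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
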