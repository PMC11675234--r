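Package: sdscan
Title: Mapping Sex-Determination Regions and Developing PCR Sex Markers
    from Population Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for locating a sex-determination region from a
    case/control resequencing panel and turning it into practical PCR
    sex markers. Provides GATK-style hard filtering of variant sites,
    an allelic chi-square association scan of genotype on phenotypic
    sex, a per-SNP XY/ZW genotype-concordance scan that infers the
    heterogametic system and calls the sex-determination interval,
    screening of sex-linked indels with in-silico PCR modelling of
    allele-specific product sizes and assay accuracy, and k-mer
    coverage-peak genome-size estimation. A seeded synthetic-data
    generator emulates a sexed diploid resequencing panel (VCF,
    phenotype table, reference FASTA) so the whole pipeline runs and is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    stringi,
    readr,
    ggplot2,
    generics,
    jsonlite,
    vcfR,
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
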