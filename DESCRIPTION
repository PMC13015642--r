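Package: somaticsift
Title: Purity-Aware Somatic CNV, LoH, Methylation and HLA Imbalance
    Analysis from Long-Read Summaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tumor purity-aware somatic analysis of long-read sequencing
    summaries. Calls somatic copy-number variants and loss-of-heterozygosity
    regions from binned coverage and SNV allele fractions with an explicit
    tumor/normal mixture model; calls cancer differentially methylated
    regions over fixed genomic windows with a cohort-calibrated threshold;
    compares allele-specific methylation across haplotypes over a gene
    panel; scores HLA loss of heterozygosity from per-allele read counts;
    subtracts germline structural variants to obtain somatic calls; and
    simulates tumor/normal pairs with planted events across an in-silico
    purity titration ladder so every component is testable against known
    ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
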