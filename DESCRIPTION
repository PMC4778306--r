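Package: rilqtl
Title: Recombination Bin Maps and QTL Scans for Low-Coverage RIL Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for taking sparse genotyping-by-sequencing SNP calls from a
    biparental recombinant inbred line (RIL) population to an ultra-high-density
    recombination bin map and multi-environment QTL results. Includes a forward
    simulator of single-seed-descent RIL genomes with GBS-like observation noise
    and planted QTL; chi-square segregation filtering; sliding-window genotype
    calling (15-SNP windows, 11-of-15 homozygosity rule) with breakpoint
    localization; 100-Kb recombination bin construction; genetic map estimation
    with the Haldane-Waddington RIL correction and Kosambi map function;
    Haley-Knott-style single-QTL regression scans with permutation thresholds,
    1.5-LOD support intervals, additive effects and PVE; stable and pleiotropic
    QTL integration; and ANOVA variance components with broad-sense
    heritability on the multi-environment line-mean basis.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    BiocGenerics
Config/testthat/edition: 3
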