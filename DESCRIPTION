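Package: mutmapr
Title: Bulked-Segregant SNP-Index Mapping of EMS-Induced Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for MutMap-style mapping of recessive EMS-induced mutations
    from phenotype-selected F2 bulks. Simulates mutagenized mapping populations
    (Haldane meiosis, recessive phenotyping, bulked sequencing at Poisson depth),
    computes per-site SNP-index and delta SNP-index statistics with depth-aware
    filters, derives sliding-window confidence thresholds from a simulated null,
    calls candidate intervals, classifies candidate variants by codon-level
    consequence (stop gain/loss, nonsynonymous, splice site), and provides the
    supporting screens: 3:1 segregation chi-square test, fold-change plus exact
    Wilcoxon rank-sum screening of metabolite abundances, and log2 expression
    ratios for gene-family comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    grDevices,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
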