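Package: methylscreen
Title: Genomic-Block Methylation Analysis and Methylation-Silencing Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of CpG-island promoter hypermethylation in tumor cohorts
    profiled on methylation beadarrays. Assembles CpG probes into genomic
    blocks defined by gene, TSS-relative category and CpG-island relation,
    summarizes them by mean beta value, and calls three-state methylation
    status with material-specific thresholds. Provides screens for aberrantly
    methylated blocks against normal controls, hierarchical clustering of
    samples over variable or normally-unmethylated CpG-island blocks, an
    integrated chemical-genomic screen for methylation-silenced genes
    re-activated by the demethylating agent 5-aza-2'-deoxycytidine,
    percentage-of-methylated-reference (PMR) quantification from qMSP molecule
    counts with Alu normalization, and classification of clonal versus
    parallel evolution of primary-metastasis pairs from shared and private
    aberrant promoter methylation. A synthetic-data generator with planted
    ground truth supports end-to-end testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
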