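Package: fragmark
Title: Fragment-Level Methylation Marker Discovery and cfDNA Lung Cancer Subtyping
Version: 0.1.0
Authors@R:
    person("fragmark", "developers", email = "fragmark@example.org", role = c("aut", "cre"))
Description: Tools for fragment-level (alpha-value) analysis of reduced
    representation bisulfite sequencing (RRBS) and cfMethyl-Seq data.
    Implements in-silico MspI digestion of a genome into CpG-enriched
    analysis regions, discovery of subtype-specific hypo- and
    hypermethylation markers from tissue cohorts with a noncancer plasma
    background filter, size-constrained K-means merging of markers into
    robust cfDNA features, an L2-penalised logistic classifier with
    cross-validation and DeLong confidence intervals for distinguishing
    lung adenocarcinoma (LUAD) from lung squamous cell carcinoma (LUSC),
    marker validation against methylation array and expression data, copy
    number thresholding utilities, and a fully seeded synthetic-data
    generator emulating tumor purity, subclonal heterogeneity and plasma
    tumor-fraction mixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
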