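Package: onekaryo
Title: Joint Copy-Number, Copy-Neutral LOH and Mutation Profiling from
    Backbone-SNP Targeted Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects somatic copy-number alterations (deletions, duplications,
    whole-chromosome losses and gains), copy-neutral loss of heterozygosity and
    small-variant profiles from a single targeted sequencing run that combines a
    gene panel with a genome-wide backbone of high-minor-allele-frequency SNPs.
    Provides a mirrored B-allele-frequency engine with closed-form expected
    values per lesion type and clonal-fraction estimation by their inversion, a
    reference-normalized read-depth caller with least-squares changepoint
    segmentation, an integrator that reconciles depth and allelic-imbalance
    evidence (including BAF-only rescue of depth-silent lesions and
    chromothripsis flagging), a tumor-only variant filtering and co-occurrence
    workflow, and IPSS-R/CPSS prognostic scoring for myelodysplastic syndromes
    and chronic myelomonocytic leukemia, including their molecular extensions.
    A fully seeded synthetic-data generator emulates the assay for validation.
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
    withr,
    yaml
Suggests:
    optparse,
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
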