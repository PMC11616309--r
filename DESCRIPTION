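Package: sircle
Title: Signature Regulatory Clustering for Gene-Level Multi-Omics Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates DNA methylation, RNA-seq and proteomics differential
    results at the gene level by assigning each gene a regulatory "flow"
    across the three layers and collapsing the 54 possible flows into named
    regulatory clusters (Regulation Groupings RG2/RG3/RG4). Includes CpG to
    gene collapsing, detection-based background filtering, cluster-wise
    over-representation analysis, transcription-factor regulon enrichment
    with mode-of-regulation agreement, and a small per-cluster MMD-regularised
    variational autoencoder that compresses seven per-gene-per-patient
    features into one integrated value on which patient-subgroup statistics
    (Mann-Whitney U or Welch t, BH-corrected within cluster) are computed.
    A synthetic matched tumour/normal cohort simulator with planted
    regulatory flows and subgroup effects supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
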