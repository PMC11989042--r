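Package: stratiquant
Title: Single-Cell Quantification of Proliferation and Stemness
    Organization in Stratified Squamous Epithelium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: In-situ single-cell analysis of multiplex immunofluorescence
    sections of stratified squamous epithelium. Provides nuclear
    segmentation and per-cell intensity extraction, basement-membrane
    estimation with basal/parabasal/suprabasal layer assignment and
    delamination detection, reference-protein (histone H1) and
    reference-cell (stromal) normalization, mixture-model intensity
    gating, basal-marker capture and concordance statistics, fold-change
    and delamination-proliferation summaries, Gaussian-mixture clustering
    of basal subpopulations, proximity ligation assay (PLA) puncta
    counting with normal-to-carcinoma progression statistics, and
    cross-dataset consensus logic for single-cell RNA-seq marker lists.
    A synthetic tissue-section generator with full ground truth encodes
    species- and disease-stage-specific organization profiles so that
    every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    fgsea,
    jsonlite,
    mclust,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
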