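Package: mcprogram
Title: Multicellular Program Inference and Patient Mapping for Autoimmune Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers coordinated multicellular gene-expression programs from
    pseudobulk views of single-cell cohorts and maps them across data
    modalities. Provides pseudobulk aggregation and quality control,
    a deterministic multi-group multi-view factorization with per-cell-type
    variance decomposition, weighted gene-set activity scoring (univariate
    linear model), cross-validated ridge dependency networks between cell
    types, archetypal analysis of single-cell state spaces with convex-hull
    patient projection, ligand-receptor interaction scoring and filtering,
    flare-risk survival modelling on longitudinal visits, and bivariate
    Moran's I spatial co-localization on spot-based slides. A synthetic-data
    generator with planted ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    survival,
    ranger
Suggests:
    testthat (>= 3.0.0),
    ape,
    sandwich,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
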