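Package: MammoMIL
Title: Clustering-Constrained Attention Multiple Instance Learning for
    Two-View Mammography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Weakly supervised classification of full-field digital
    mammograms labelled only at image level. Images are tiled into
    overlapping square patches that form a bag; a gated-attention pooling
    head aggregates per-patch embeddings into a bag embedding, a
    clustering-constrained instance classifier refines the attention on the
    top- and bottom-attended patches, and per-patch attention weights are
    rendered into heatmaps for coarse lesion localisation. Includes
    artifact-aware preprocessing (chest-wall edge-band removal, orientation
    normalisation, half-resolution resizing, craniocaudal + mediolateral
    oblique view concatenation), patient-wise stratified cross-validation,
    class-balanced oversampling, SGD training with gradient accumulation
    and early stopping, threshold optimisation by the Youden index, and a
    synthetic breast-phantom generator with known lesion masks so the whole
    pipeline can be exercised and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'MammoMIL-package.R'
    'bagging.R'
    'synthetic.R'
    'heatmap.R'
    'extractor.R'
    'mil.R'
    'training.R'
    'imaging.R'
    'pipeline.R'
    'cli.R'
    'evaluation.R'
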