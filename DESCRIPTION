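Package: corrtaste
Title: Correlative Analysis of Taste-Cell Calcium Imaging and Multi-Round smFISH
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links in vivo taste-cell calcium responses to single-cell mRNA and
    protein identity. Provides ratiometric (GCaMP/tdTomato) trace extraction
    with rigid motion correction, dF/F and Z-score responsiveness
    classification and the sweet-umami response index; B-spline non-rigid
    registration of in vivo images to fixed round-1 histology with
    deformation-field quality control; nuclear-anchored rigid registration of
    later smFISH rounds; difference-of-Gaussians single-molecule FISH spot
    detection with subpixel Gaussian fitting and digital per-cell counting;
    watershed cell segmentation with mask propagation; and the correlative
    statistics (ROC marker-function linking, receptor-class calling against a
    CA4-positive negative control, afferent-nerve adjacency and dual-tuning
    attribution). A synthetic-data module generates ground-truthed functional
    movies and multi-round histology so the whole pipeline is testable without
    any acquisition.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'corrtaste-package.R'
    'utils-image.R'
    'AllClasses.R'
    'transforms.R'
    'synthetic-scene.R'
    'synthetic-movie.R'
    'synthetic-rounds.R'
    'synthetic-cohort.R'
    'traces.R'
    'registration-rigid.R'
    'registration-nonrigid.R'
    'registration-qc.R'
    'segmentation.R'
    'spots.R'
    'roc.R'
    'integration.R'
    'io.R'
    'pipeline.R'
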