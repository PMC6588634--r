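Package: cellmorph
Title: Multi-View Cellular Morphology Networks for Neuron Reconstructions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for morphology analysis of volume-EM cell reconstructions
    based on multi-view 2D depth-map projections. Provides PCA-aligned
    orthographic rendering of triangle meshes at homogeneously sampled
    locations, cellular morphology neural networks (CMNs) for glia,
    compartment and cell-type classification, unsupervised Neuron2vec
    triplet-loss embeddings, a graph heuristic that splits glia-neuron merge
    errors in supervoxel graphs, a 23-feature skeleton descriptor with a
    random-forest baseline, and sub-micron semantic segmentation of cell
    surfaces via face-ID back-mapping. A seeded synthetic-data module
    generates neuron-like and glia-like meshes, supervoxel decompositions,
    skeletons and organelle volumes so the whole pipeline runs without an EM
    volume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'cellmorph-package.R'
    'geometry-utils.R'
    'nn-core.R'
    'nn-losses.R'
    'cmn-arch.R'
    'cmn-train.R'
    'skeleton.R'
    'features.R'
    'geometry-io.R'
    'glia.R'
    'metrics.R'
    'nview.R'
    'synthetic-mesh.R'
    'synthetic-neuron.R'
    'synthetic-voxel.R'
    'organelles.R'
    'synthetic-glia.R'
    'sampling.R'
    'triplet.R'
    'pipeline.R'
    'render.R'
    'surface.R'
    'volume-io.R'
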