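Package: SurfaceMatch
Title: Geodesic Patch Descriptors for Protein Molecular Surface Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds triangulated molecular surfaces from protein structures,
    featurizes them with geometric (shape index, mean curvature) and chemical
    (charge, hydropathy, hydrogen-bond potential) per-vertex channels, and
    encodes fixed-radius geodesic surface patches into fixed-dimension
    descriptors with a geodesic convolutional network trained by
    self-supervised contrastive learning. Descriptor-distance search, hit
    grouping and extension, interface similarity scores (reciprocal-mean,
    joint product, coverage ratio), and rigid surface alignment (centroid
    translation followed by rotational gradient descent against an RMSD loss)
    support interface classification, epitope and paratope clustering, and
    grafting of binding partners onto matched surface regions. A synthetic
    data module generates parametric meshes, spatially correlated feature
    fields, planted similar-region mesh pairs, and toy peptides for fully
    self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    optparse,
    pROC
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
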