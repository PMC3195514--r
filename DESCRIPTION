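Package: vasctree
Title: Hierarchical Vascular Tree Models for Retinal Image Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds a hierarchical tree model of the retinal vascular
    network from a vessel centerline raster, a vessel mask, and a table of
    bifurcation/branch/crossover landmarks: one binary tree per vessel
    rooted on the optic-disc boundary, each node holding a vessel segment
    and its five rotation-, translation- and scale-invariant features
    (length-to-width ratio, bifurcation-vs-branch code, crossover flag and
    relative crossover position, parent-daughter acute angle). Tree models
    from two images of the same retina are matched by preorder,
    tolerance-based feature-vector comparison, yielding node-count
    distances and a vessel-to-vessel correspondence that is robust to
    image rotation. A seeded synthetic vascular-scene generator with exact
    ground-truth topology replaces upstream segmentation and landmark
    detection so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    png,
    withr,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'raster.R'
    'accessors.R'
    'synthetic.R'
    'io.R'
    'fragment.R'
    'trace.R'
    'build.R'
    'features.R'
    'matcher.R'
    'rotate-eval.R'
    'cli.R'
    'vasctree-package.R'
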