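Package: vascmorph
Title: Vascular Phantoms, Stack Optimization and Skeleton-Graph Morphometry
    for Micro-Optical Brain Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative analysis of brain vasculature in
    high-resolution micro-optical sectioning image stacks. Provides a
    ground-truthed synthetic vascular phantom generator (rake-like trunk
    systems with comb-like capillary beds, soma blobs, stripe and staining
    artifacts), an image-optimization chain (stripe baseline correction,
    morphological background flattening, bilateral denoising, linear
    contrast stretch), gray-value vessel extraction with density maps and
    maximum-intensity projections, centerline skeletonization into a
    node/segment graph with diameter, branch-level and branch-angle
    morphometry per anatomical region, virtual vascular endoscopy
    (iso-surface meshing, per-vertex lumen-distance scalar field,
    parallel-transport camera paths), and group comparison of wild-type
    versus disease-model phantom cohorts with unpaired t-tests.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
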