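Package: livervasc
Title: Quantification of Hepatic Vascular and Parenchymal Regeneration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Morphometric analysis of hepatic vascular trees from 3D
    micro-CT-like volumes. Provides a synthetic vascular phantom generator
    (strictly bifurcative trees with Murray-law radii inside an ellipsoidal
    liver domain, growth transforms, and a cylinder voxelizer), threshold
    segmentation and voxel volumetry, 3D medial-axis skeletonization with
    distance-transform radius estimation, conversion to strictly bifurcative
    cylinder trees with Strahler orders and anatomical lobe labels,
    nearest-vessel territory computation and virtual resection, the
    circumscribed/cumulative/density geometric parameters of regenerating
    livers, and the comparison of observed growth against hypothetical
    isotropic expansion with a visibility-threshold restriction.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
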