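Package: craniorays
Title: Raycast Shape Descriptors and Neural Classification of Infant Head Shapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying infant cranial shape from 3D surface meshes.
    A hemi-icosphere of unit ray directions is cast from the sella turcica to
    the outer head surface, producing a fixed-length ray-cast shape descriptor;
    descriptors are mirrored across the mid-sagittal plane for augmentation,
    standardized per ray, and classified into healthy, scaphocephaly,
    trigonocephaly and anterior plagiocephaly by a small feed-forward neural
    network evaluated with linked stratified k-fold cross-validation. Includes
    a parametric synthetic head-shape generator so the full pipeline can be
    exercised without clinical data, plus readers and writers for PLY, OBJ and
    STL triangle meshes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
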