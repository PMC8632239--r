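Package: NaviMargin
Title: Virtual Cutting-Plane Margin Analysis for Navigated Transnasal Phantom Surgery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthetic-phantom pipeline for quantifying posterior-margin
    delineation in maxillary-tumor models under surgical navigation. Generates
    voxelized skull/tumor/carotid phantoms with controlled tumor-carotid
    clearances, synthesizes CBCT-like volumes, segments structures and computes
    signed Euclidean distance fields, builds a dilation-based carotid proximity
    alert cloud, performs paired-point rigid registration with fiducial
    registration error gating, samples simulated surgeon pointer poses in
    unguided and navigation-guided settings, classifies 30 x 11 mm virtual
    cutting-plane areas into joint tumor/carotid distance zones, and compares
    guidance settings with Kruskal-Wallis, Steel-Dwass-Critchlow-Fligner
    post-hoc and Fisher exact statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Rcpp,
    jsonlite,
    yaml,
    png,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
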