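Package: tfusplan
Title: Tractography-Based Target Planning for MR-Guided Focused Ultrasound
    Thalamotomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic stereotactic planning pipeline for transcranial
    MR-guided focused ultrasound (tcMRgFUS) thalamotomy in essential tremor.
    Computes the AC-PC based geometric standard target coordinate, performs
    rigid image registration with a normalized-gradient-fields distance,
    preprocesses diffusion-weighted images (Lanczos-3 supersampling,
    Gaussian smoothing, Stejskal-Tanner tensor estimation), runs
    atlas-adaptive deterministic streamline tractography of the
    cerebellothalamic, pallidothalamic, corticospinal and medial lemniscus
    bundles with seed/include/exclude filtering and a minimum-fiber retry
    loop, converts bundles to thresholded visitation probability maps, and
    evaluates treatment-point deviations, bundle distances and Dice
    overlaps. Fully synthetic tensor phantoms make every stage testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
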