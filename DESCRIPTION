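Package: plaquescan
Title: Carotid Plaque Segmentation, Morphology and Biomechanical Surrogates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Structural assessment of carotid atherosclerotic plaque from
    multi-contrast (T1-, T2-, proton-density- and time-of-flight-weighted)
    volumetric images. Provides a synthetic carotid-bifurcation phantom
    generator with ground-truth tissue labels and physiological waveforms;
    least-cost-path (Dijkstra) lumen centerline extraction; per-slice active
    contour lumen segmentation and circle-model dynamic-programming outer wall
    tracing; k-means tissue clustering into arterial wall, lipid and
    calcification; plaque morphology quantification (component volumes,
    thinnest fibrous cap thickness, NASCET stenosis degree); material mapping
    of tissue elastic moduli onto tetrahedral meshes with a transitional
    interpolation region; quasi-steady Poiseuille wall-shear-stress and
    Laplace-law wall-stress surrogates with time-averaged wall shear stress,
    oscillatory shear index and region-of-interest statistics; and a
    reproducible end-to-end reporting pipeline with cross-case comparison.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
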