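Package: toothrecon
Title: Parametric 3D Tooth Reconstruction from Panoramic Radiograph Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs three-dimensional parametric tooth models (single-
    and multi-rooted classes) from two-dimensional panoramic-radiograph
    measurements, and provides the full validation tool chain around them:
    a B-spline curve and surface kernel (lofts, Coons patches, surfaces of
    revolution) with triangle-mesh tessellation; mesh metrology that
    re-measures the anatomical control parameters (equator, cement-enamel
    junction, root widths, crown and tooth heights, furcation height);
    Dahlberg repeatability error, multiplicative scale calibration and a
    nonparametric method-comparison protocol (Shapiro-Wilk, Wilcoxon
    signed-rank, Kruskal-Wallis); iso-surface extraction from scalar
    volumes with superimposition-based segmentation-threshold calibration;
    best-fit rigid registration (iterative closest point) with signed
    surface-deviation maps and per-region deviation reports; and a
    synthetic-patient generator emulating CBCT-like segmented meshes,
    blurred occupancy volumes and multi-method measurement tables with
    magnification and landmark noise.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
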