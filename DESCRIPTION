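Package: ctmaxslope
Title: Maximum-Slope CT Perfusion from Full Curves or Two Scan Phases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Organ perfusion estimation from dynamic contrast-enhanced CT
    using the maximum slope method. Models time-enhancement curves with the
    Madsen gamma-variate function and computes perfusion either from the full
    sampled curve (smoothing-spline maximum slope) or from just two scan
    phases (baseline and peak enhancement) combined with the feeding-vessel
    peak enhancement and bolus-shape parameter. Includes a seeded generator
    of synthetic dynamic-CT studies for validation, Bland-Altman and
    regression method comparison, image-quality metrics, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    yaml
Config/testthat/edition: 3
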