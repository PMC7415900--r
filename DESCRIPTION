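Package: octadegen
Title: Longitudinal OCT Angiography Analysis of Rodent Retinal Degeneration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies depth-resolved optical coherence tomography angiography
    (OCTA) of the degenerating rodent retina. Implements an intensity-based
    vessel index for the superficial and deep retinal plexuses, a gradient
    sharpness index for the choroidal plexus that tracks loss of retinal
    pigment epithelium scattering, vertical-gradient retinal layer boundary
    detection on cross-sectional B-scans with sub-pixel refinement, and a
    repeated-measures inferential procedure (two-way within-subject ANOVA with
    Greenhouse-Geisser correction, Bonferroni-adjusted consecutive-week
    contrasts, and an orthogonal linear trend test). A seeded synthetic cohort
    generator emulates Royal College of Surgeons (RCS) rat degeneration with
    ground truth, so the full pipeline runs and is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    yaml,
    tiff,
    png,
    ggplot2,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
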