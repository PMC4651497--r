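Package: surequant
Title: Subject-Registered Voxelwise Quantification of Diffusion MRI Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxelwise comparison of a single subject's diffusion metric map
    (fractional anisotropy) against a normative control group, with
    cluster-extent inference restricted to template white matter. Implements
    both registration targets for the analysis -- a canonical atlas-style
    template (atlas-based registration) and the subject of interest itself
    (subject-based registration, in which the subject is never resampled) --
    together with quantification of gray-matter/CSF misregistration onto
    template white matter, a deformable-registration error simulator with
    controlled residual amplitude, a synthetic brain phantom cohort
    generator, paired Wilcoxon signed-rank testing, and cluster-size
    threshold calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    tibble,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
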