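Package: normdev
Title: Voxel-Wise Normative Modelling of Brain Structural Heterogeneity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gaussian-process normative models of voxel-wise gray-matter
    volume on age and sex, with individual deviation (Z) maps, extreme-value
    deviation statistics, nonparametric group comparisons, permutation-based
    voxel-wise general linear model inference, and within-group overlap
    mapping of extreme deviations. Includes a synthetic cohort generator
    that emulates smoothed voxel-based-morphometry data with idiosyncratic
    focal lesions, so the full case-control heterogeneity analysis can be
    run and calibrated end to end without clinical MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
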