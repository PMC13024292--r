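Package: spinetrack
Title: Cervical Spine Motion Analysis from Dynamic Radiograph Segmentations
Version: 0.1.0
Authors@R:
    person("M.", "de Vries", email = "mdevries@example.org", role = c("aut", "cre"))
Description: Tools for quantitative motion analysis of the cervical spine from
    per-frame multi-label vertebra segmentation masks of dynamic X-ray
    recordings. Builds per-recording rigid mean shapes of each vertebra,
    tracks per-frame vertebral rotation by overlap-maximising template
    fitting, derives inter-vertebral (segmental) rotation traces, segmental
    range of motion, and motion-pattern curves, and quantifies agreement
    between predicted and reference kinematics with ICC(3,1). Includes
    segmentation-quality metrics (Dice, Jaccard, 95th-percentile Hausdorff
    distance), masked histogram equalization and histogram matching for
    radiograph preprocessing, a synthetic articulated phantom generator with
    analytic ground-truth kinematics, and a stage-composable command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
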