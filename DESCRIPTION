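Package: relaxnorm
Title: Voxel-Wise Normative R1 Relaxometry and Subject-Specific Deviation Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds voxel-wise age-adjusted normative atlases of the MRI
    longitudinal relaxation rate R1 from a healthy control cohort and maps
    individual deviations as z-scores with cluster-extent correction, the
    approach used to localize excess manganese accumulation in the brains of
    occupationally exposed workers. Includes two-point variable-flip-angle
    R1 fitting from spoiled gradient-echo signals, a synthetic brain phantom
    generator for end-to-end testing without MRI data, k-fold cross-validated
    false-positive-rate estimation, and cumulative-exposure-index based
    classification of exposed subjects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
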