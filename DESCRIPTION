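Package: agedetrend
Title: Control-Only Voxel-Wise Age Correction for Grey-Matter Maps
Version: 0.1.0
Authors@R: person("VBM", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Voxel-wise linear age detrending of grey-matter density maps
    estimated on healthy controls only and applied to all subjects before
    statistical evaluation, together with the two evaluation engines needed
    to validate such a correction: mass-univariate voxel-based-morphometry
    style group contrasts with permutation cluster-extent family-wise-error
    correction, and a split-half linear support-vector-machine
    classification harness with repeated-permutation accuracy statistics.
    Includes a synthetic phantom-cohort generator with known baseline, age
    slope, disease offset and noise so every stage is testable without any
    image download, a minimal self-contained NIfTI-1 reader/writer, and
    cohort summary statistics (pooled two-sample t, Pearson chi-square,
    one-way ANOVA with Bonferroni post-hocs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
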