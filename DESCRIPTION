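Package: germscreen
Title: Germination-Stage Salt-Tolerance Screening of Germplasm Panels
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluates salt tolerance of crop germplasm panels at the seed
    germination stage from daily germination counts and seedling endpoint
    measurements. Computes seven germination and seedling traits (germination
    rate, index, energy, root length, vigor index, fresh weight, water
    content), per-trait salt-tolerance indices (stress/control ratios),
    fuzzy membership-function values normalized across the panel, a
    five-grade mean +/- 1.64 SD tolerance classification, and a multiple
    linear regression tolerance score for grading new germplasms without
    re-normalizing a full panel. Includes a stochastic germination
    time-course simulator for generating germplasm panels with known latent
    tolerance, used for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
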