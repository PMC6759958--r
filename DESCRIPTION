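Package: phtremor
Title: Pharmacological fMRI Analysis of Drug-Induced Tremor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pharmacological fMRI experiments on
    drug-induced tremor in large-animal models. Provides a synthetic-data
    generator with known ground truth (BOLD sessions, heart-rate traces,
    accelerometer recordings), heart-rate nuisance regression to remove
    injection-related cardiovascular artifact, voxelwise GLM activation
    mapping with an HRF-convolved injection-block regressor (including
    block-length sweeps, group and paired t statistics, FDR thresholding
    and cluster peak tables), a spectral accelerometer tremor index with
    session-level tolerance statistics, ROI partial-correlation network
    analysis with permutation significance, and voxelwise regression of
    activation strength on tremor severity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
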