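Package: ionvol
Title: Partial Molar Volumes of Electrolytes and Single Ions from Dilute
    Densimetry and Solvation Snapshots
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts partial molar volumes and thermal-expansion
    coefficients of strong electrolytes from dilute-solution density data
    using a Pitzer-type model with the Debye-Hueckel limiting slope for
    volumes, decomposes salt volumes into a self-consistent set of
    single-ion volumes under a literature proton-volume constraint, and
    estimates ionic volumes from molecular-dynamics solvation snapshots
    via distance-orientation maps and the V(N) sphere-volume intercept
    estimator. Includes synthetic-data generators emulating densimeter
    campaigns and solvation-shell trajectories so every stage of the
    pipeline can be validated by parameter recovery.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
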