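Package: facefd
Title: Focus Distance Estimation from Facial Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates the subject-to-camera focus distance of frontal and
    profile face photographs from anthropometric landmark lengths (the
    palpebral fissure for frontal views, the pupil-chord-to-stomion distance
    for profile views) and pinhole camera geometry. Includes a synthetic
    photogrammetry study generator emulating multi-camera DSLR and smartphone
    validation designs, grouped error statistics (mean signed error, MAE,
    MAE%, SEE), and a perspective-distortion tolerance check for craniofacial
    superimposition casework.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    withr,
    yaml,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
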