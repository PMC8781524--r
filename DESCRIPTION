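Package: psoct
Title: Simulation and Birefringence Analysis of Polarization-Sensitive OCT
    B-Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Forward simulation of layered, scattering, birefringent samples
    imaged with polarization-sensitive optical coherence tomography (PS-OCT),
    and the inverse analysis that recovers per-layer birefringence from
    paired intensity/retardation B-scans: Otsu surface segmentation,
    A-scan flattening, lateral averaging, and linear fitting of cumulative
    phase retardation versus depth. Includes stretch-induced (photoelastic)
    birefringence calibration for PDMS-like elastomers, stress computation
    for clamped stretch experiments, and an end-to-end pipeline that
    validates layered bladder-wall phantom designs (normal versus
    carcinoma-in-situ-like conditions) against design criteria.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    yaml
Suggests:
    EBImage,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
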