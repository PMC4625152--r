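Package: sfhi
Title: Spatial Frequency Heterodyne X-Ray Scatter Imaging Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates grid-modulated x-ray acquisitions of
    nanoparticle-labeled digital tissue phantoms and reconstructs each
    exposure into a conventional absorption image plus horizontal and
    vertical small-angle-scatter (dark-field) images by Fourier-harmonic
    demodulation of the grid shadow. Includes region-of-interest
    enhancement statistics, integrated-optical-density and ratio-table
    arithmetic for gold-nanoparticle contrast-agent uptake, dual-modality
    colour overlays, and a reproducible end-to-end pipeline driven by a
    YAML configuration.
License: MIT
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
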