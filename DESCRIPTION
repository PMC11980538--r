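Package: niqc
Title: Automated ROI-Free Quality Control for Small-Animal MR Neuroimaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated, region-of-interest-free quality control for small-animal
    magnetic resonance neuroimaging. Discovers scans in NIfTI/BIDS trees or raw
    Bruker study folders, computes per-scan quality features (two spatial
    signal-to-noise estimators, temporal SNR, mutual-information ghost evidence
    and motion severity), flags poor-quality scans with an ensemble of five
    outlier detectors aggregated by majority vote, and writes machine-readable
    reports with slice galleries and summary figures. Includes a synthetic
    phantom and artifact simulator (noise, shading, motion, ghosts) for
    end-to-end validation without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    MASS,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
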