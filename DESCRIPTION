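Package: brainglance
Title: Atlas-Based Single-Subject Fingerprints of Volumetric Brain Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Summarizes per-subject volumetric brain maps (NIfTI) into an
    atlas-region by subject matrix and displays every subject and every
    brain area together in one mirror-symmetric grid ("brainglance"
    fingerprint). Includes eigenvector centrality mapping and regional
    homogeneity (Kendall's W) computed from 4D time series, temporal
    high-pass filtering and Gaussian smoothing, affinity-propagation
    clustering of subjects into exemplar-based subgroups with
    log-scaled row heights, and per-region statistics comparing
    native-space against template-space processing. Ships a synthetic
    phantom generator so the full pipeline runs without any imaging
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    RNifti,
    generics,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
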