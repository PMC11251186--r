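Package: c4bpquant
Title: Quantification of Co-Occurring C4b-Binding Protein Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Single-particle mass analysis and plasma monitoring of the
    co-occurring higher-order assemblies of human C4b-binding protein
    (C4BP). Converts charge detection mass spectrometry (CDMS) single-ion
    events and mass photometry (MP) contrasts into calibrated masses,
    deconvolves mass histograms by Gaussian-mixture expectation
    maximization, assigns subunit stoichiometries to fitted components by
    bounded enumeration, and infers protein S occupancy from paired
    native/acidified measurements. Companion stages quantify site-specific
    N-glycosylation from glycopeptide PSM tables, validate cross-linking
    MS restraints against multi-chain coordinate models, and estimate
    C4BP alpha/beta stoichiometry and unbound protein S in plasma via
    reference-protein log-log regression of label-free quantification
    intensities. A synthetic-data module generates every input with the
    statistical structure the analysis assumes, so the full pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    Biostrings,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
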