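Package: raphemap
Title: Analysis Pipeline for Optogenetic fMRI and Electrophysiology of the
    Dorsal Raphe Serotonin Circuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for block-design optogenetic fMRI (ofMRI) and paired
    extracellular electrophysiology of the dorsal raphe nucleus (DRN)
    serotonin system. Provides synthetic-data generators with known ground
    truth (CBV region-of-interest time series, multichannel probe
    recordings, atlas maps), spike detection and refractory-constrained
    agglomerative sorting, Morlet-wavelet LFP band-power analysis with
    network-burst statistics, gamma-HRF general linear model fitting with
    block-wise amplitude estimation, permutation-based group inference with
    cluster-extent and FDR correction, electro-vascular coupling via
    HRF-convolved band-power regressors, and structure-function correlation
    against projection-density and receptor-expression maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
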