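Package: plaslab
Title: Simulation and Analysis of Phase-Locked Acoustic Stimulation in Sleep EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for closed-loop phase-locked acoustic stimulation (PLAS)
    studies of sleep slow waves. Simulates multi-night, multichannel sleep EEG
    for healthy and cognitively impaired participant profiles (1/f background,
    frontal slow-wave events, sleep spindles, stimulation-evoked responses,
    memory trajectories, plasma amyloid-beta 42/40 ratios); implements the
    online template-correlation slow-wave peak-prediction algorithm with real
    and sham marker placement; and reproduces the downstream analysis chain:
    artifact handling and stage gating, event-related potentials with
    whole-epoch baseline correction, Morlet event-related spectral
    perturbations with dB baselining, cluster-based permutation statistics,
    stimulation-count-weighted response scores, the summed-activity statistic
    with outlier pruning, and cohort-level regressions of electrophysiological
    response on memory gains and amyloid dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
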