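Package: chaperFlow
Title: Chaperone-Reporter Flow Cytometry Kinetics and Statistics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
        role = c("aut", "cre"))
Description: Simulation and analysis of dual fluorescent-reporter flow
        cytometry time series for protein quality control studies. A
        per-cell kinetic model generates single-cell red (protein
        abundance, slow-maturing RFP fusion) and green (DnaK-promoter
        activity, fast-maturing sfGFP) fluorescence trajectories for
        panels of protein variants differing in thermodynamic
        stability, together with OD600 growth curves. Analysis tools
        cover doublet gating, per-timepoint summaries, windowed
        (relative) rate estimation, Spearman correlation tracks
        against variant melting temperature, sparsity-pruned
        variational Bayesian Gaussian mixture clustering of
        single-cell populations, logistic growth-rate inference with
        sampling-based uncertainty, and quantification of the growth
        dilution bias on fluorescence rates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tools, deSolve, minpack.lm,
        data.table, readr, yaml
Suggests: testthat (>= 3.0.0), Matrix, jsonlite
biocViews: FlowCytometry, SingleCell, Software, TimeCourse, Clustering
Config/testthat/edition: 3
RoxygenNote: 7.3.3
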