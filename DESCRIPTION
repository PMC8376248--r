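Package: EnsembleTracker
Title: Detection and Longitudinal Stability of Neuronal Ensembles from
    Binary Activity Rasters
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects neuronal ensembles in binary spike rasters from
    two-photon calcium imaging using surrogate-tested functional
    connectivity (circular-shift null model) and Jaccard-based
    hierarchical clustering of population vectors, demixes per-neuron
    ensemble membership with correlation-weighted coactivation tests,
    and quantifies ensemble stability across imaging sessions (stable
    versus transient ensembles, stable/lost/new neurons, robustness,
    network density, stimulus tuning). Includes a synthetic raster
    generator that plants ground-truth ensembles with controlled
    activity levels, cross-session neuron overlap and member turnover,
    so every stage of the pipeline can be validated without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, Clustering, Network, SingleCell, TimeCourse
RoxygenNote: 7.3.3
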