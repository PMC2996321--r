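Package: critdev
Title: Self-Organised Criticality in Developing Neuronal Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates activity-dependent neurite outgrowth in a recurrent
    network of stochastic threshold neurons whose axonal and dendritic fields
    grow towards calcium (firing-rate) homeostasis, producing the three
    developmental phases observed in dissociated cortical cultures. Provides
    the complete neuronal-avalanche analysis used to classify such systems:
    adaptive time-bin selection from the pooled inter-spike interval and the
    mean cross-correlogram, avalanche extraction, power-law regression of the
    size distribution, a scalar deviation-from-power-law measure with
    subcritical/critical/supercritical classification, and a battery of
    additional criticality tests (spatial subsampling, time-bin robustness,
    inter-avalanche scaling-function collapse, Fano-factor analysis). A
    mean-field companion gives closed-form trajectories, the steady-state
    firing rate, the nullcline (hysteresis) curve and fixed points. Includes
    raster readers/writers, electrode-selection filters for multi-electrode
    array recordings, and synthetic Poisson and branching-process raster
    generators that serve as statistical reference models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
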