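Package: fieldperm
Title: Time-Frequency Analysis and Cluster Permutation Statistics for
    Intracranial Field Potentials and Spikes
Version: 0.1.0
Authors@R:
    person("fieldperm", "developers", email = "fieldperm@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of event-related intracranial
    electrophysiology recordings (subthalamic local field potentials,
    subdural strip iEEG, and microelectrode spike trains). Provides a
    synthetic session generator with known ground-truth effects
    (event-related beta desynchronization, condition-dependent rebound,
    theta increases, within-block beta decline, cortico-subthalamic beta
    coupling, phase-locked spiking), zero-phase filtering and referencing,
    Morlet wavelet spectral decomposition with percent-change baseline
    normalization, two-level permutation statistics with exceedance-mass
    cluster correction, sliding-window coherence decomposed into phase
    synchrony and across-trial power correlation, Gaussian-kernel firing
    rates, and surrogate-normalized spike-phase locking, plus an
    end-to-end pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
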