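Package: statescape
Title: Energy-Landscape Analysis and Simulated State-Dependent
    Stimulation of Brain-State Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pairwise maximum-entropy modelling of binarised multi-region
    neural activity and analysis of the resulting energy landscape:
    local minima, basins, disconnectivity graphs, directional barriers
    and coarse-grained major brain states. Includes Metropolis
    random-walk simulation of state dynamics, an offline EEG-style
    preprocessing chain (average reference, band filtering, Hilbert
    envelopes, Hjorth derivation, binarisation), a deterministic
    simulator of closed-loop brain-state-dependent stimulation with
    Yule-Walker forward prediction and dominance-based triggering,
    virtual-lesion analysis by state-space restriction, behavioural
    percept-duration statistics with bootstrap mediation analysis, and a
    synthetic-data generator that reproduces the three-state landscape
    structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
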