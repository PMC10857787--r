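Package: arenasim
Title: Continuous-Space Simulation of Rodent Locomotion and Spatially Tuned Neurons
Version: 0.1.0
Authors@R:
    person("Arena", "Maintainers", email = "maintainers@arenasim.org", role = c("aut", "cre"))
Description: Simulates rodent-like foraging in continuous one- or
    two-dimensional arenas with walls, holes and objects, and generates
    synthetic neural activity for the standard spatially modulated cell
    types of the hippocampal formation. Locomotion follows
    Ornstein-Uhlenbeck velocity processes (Rayleigh-distributed speeds,
    normally distributed turning rates) with smooth wall repulsion and a
    tunable thigmotaxis bias. Neuron populations include place cells
    (five response profiles with euclidean, line-of-sight or geodesic
    wall geometry), grid cells, boundary/object/agent vector cells
    (allocentric or egocentric, including field-of-view tilings), head
    direction, velocity and speed cells, theta phase-precessing place
    cells, Gaussian-process random spatial fields, and trainable
    function-approximator layers. Firing rates are computed online and
    spikes are drawn from an inhomogeneous Bernoulli process; rate maps
    can be evaluated analytically or estimated from occupancy-weighted
    histograms.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
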