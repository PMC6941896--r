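Package: echosteer
Title: Closed-Loop Simulation of Biosonar Obstacle Avoidance with Binaural Level Cues
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An agent-based, closed-loop simulator of sonar-guided obstacle
    avoidance in cluttered two-dimensional scenes. Synthetic binaural echo
    trains from point-scatterer ensembles (ivy-wrapped poles in a rectangular
    arena, egg-carton-lined corridor walls) are processed by a single-channel
    gammatone cochlear model into two minimal cues: the distance to the
    nearest reflector, taken from the first supra-threshold echo, and the
    interaural level difference of the echo-train onset. These cues drive
    either a Fixed Head steering law, a Delayed Linear Adaptive Law (DLAL)
    gaze-scanning controller, or a Random Walk baseline. The package runs
    seeded arena and corridor experiments, computes collision-rate and
    trajectory metrics, and checks the steering laws against a g-force
    turn-rate feasibility bound.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
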