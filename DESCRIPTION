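Package: flyhalt
Title: Connectome-Constrained Spiking Simulation and Halting-Behavior Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how walking insects stop. Implements a
    connectome-constrained leaky integrate-and-fire network simulator with
    in-silico optogenetic stimulation and silencing protocols, signed
    synapse-count connectivity derived from neurotransmitter predictions, and
    thresholded wiring-diagram export; quantification of 3D leg kinematics on
    a spherical treadmill (sphere fitting, swing/stance segmentation,
    swing-initiation-zone statistics, stopping bouts, grooming stability);
    free-walking arena metrics (velocities, pivots, stops, sucrose preference,
    food-zone interactions); calcium-trace analyses (delta-F/F under several
    baseline conventions, response areas, ratiometric z-scores, pixel-wise
    behavior correlation, lagged activity-velocity cross-correlation); and
    synthetic-data generators that plant known circuit motifs, gait phases,
    behavioral bouts and activity couplings for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
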