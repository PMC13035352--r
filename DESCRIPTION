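Package: respdmd
Title: Dynamic Mode Decomposition for Airway Flow and Aerosol Deposition
Version: 0.1.0
Authors@R:
    person("respdmd", "Developers", email = "respdmd@example.org",
           role = c("aut", "cre"))
Description: Reduced-order modelling of pulsatile airway flow and inhaled
    particle transport with exact dynamic mode decomposition (DMD).
    Snapshot decks of fluid velocity or Lagrangian particle positions are
    decomposed into spatial modes with fixed complex frequencies via a
    best-fit linear propagator; a parametric extension linearly blends
    reduced Koopman operators, POD bases and modal amplitudes between two
    trained inlet flow rates to reconstruct the field at an untrained rate.
    Includes radial deposition statistics (uniform-bin probability
    densities about the carina and Bhattacharyya overlap), relative L2
    error metrics with region (wall/outlet) breakdowns, a synthetic
    generator for bifurcating-airway snapshot decks and particle ensembles,
    snapshot/model serialization, and phase-oriented pipeline drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
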