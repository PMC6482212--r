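Package: cvnet
Title: Neural-Network Approximation of Collective Variables with PLUMED Export
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Trains small feed-forward neural networks to approximate a
    precomputed collective variable (for example a non-linear embedding or a
    solvent-accessible surface area) from superposed, box-scaled Cartesian
    coordinates of a structure ensemble, and serializes the trained network
    into a PLUMED input file so the collective variable can be monitored or
    biased in molecular simulations.  Includes readers for PDB, DCD and TRR
    ensembles, a Kabsch superposition and box-scaling preprocessor, analytic
    input gradients (the prerequisite for biasing), an internal evaluator for
    the emitted PLUMED dialect that stands in for the plumed driver check, and
    synthetic conformer generators with oracle collective variables (radius of
    gyration, Shrake-Rupley surface area) so the whole train-export-verify
    loop runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
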