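Package: memregen
Title: Cell-Memory Model of Pattern Regeneration on a Square Lattice
Version: 1.0.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulator for regeneration of cell structures driven by cell
    memory of a pre-amputation signal distribution. Cells occupy nodes of a
    2D integer lattice and emit signals that decay with distance
    (polynomial or exponential kernels). After amputation, the remaining
    control cells remember their old total signal and a greedy algorithm
    places new cells, one per step, so the received signal converges back
    to the remembered value, restoring the original shape exactly within
    the model's validity range. Includes shape and fixture generators,
    amputation with blastema identification, two greedy selection rules,
    an admissibility constraint forbidding signal overshoot, a
    morphogenesis mode growing structures from an organizing center with a
    prescribed target signal, closed-form analytic oracles (two-circle
    restoration of a single removed cell, nonlinear-diffusion steady state
    with power-law decay), CSV and JSON serialization, PNG rendering and a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
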