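Package: fpnash
Title: Fokker-Planck Nash Games for Pedestrian Collision Avoidance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the avoidance dynamics of two interacting pedestrians as an
    open-loop Nash differential game governed by Fokker-Planck equations. Each
    pedestrian's position is a stochastic process whose probability density
    evolves under a controlled convection-diffusion equation with zero-flux
    (reflecting) boundary conditions, discretized by a conservative,
    positivity-preserving exponentially fitted finite-volume scheme. Avoidance
    strategies arise as a Nash equilibrium computed by minimizing a composite
    cost functional (terminal target, control effort, collision overlap) with an
    adjoint-based, H1-smoothed, projected gradient method. Includes a reflected
    Euler-Maruyama Monte Carlo simulator for particle-level cross-validation, a
    registry of four benchmark crossing scenarios, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
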