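Package: tumbleturn
Title: Run-and-Tumble-Turn Particle Dynamics: Simulation and Continuum Theory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based and continuum modelling of anisotropic self-propelled
    particles that perform sharp 90-degree "tumble-turns". Provides the
    four-well angular steering potential with dilogarithm smoothing, Kramers
    theory for the tumble-turn rate and the derived time and length scales,
    Euler-Maruyama integration of the solitary-particle Langevin equations
    (compiled, with reproducible per-particle random streams), trajectory
    statistics (displacement moments, non-Gaussian parameter, tangent
    correlations, squarishness), the four-direction spinor master equation
    solved exactly per Fourier mode, its anisotropic sixth-order
    hydrodynamic limit with closed-form densities and axis/diagonal odds,
    and a many-body simulator with Hertzian repulsion and range-limited
    alignment for studying flocking and density heterogeneity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
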