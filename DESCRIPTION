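Package: magsteer
Title: Model-Based Steering and Focusing of Magnetic Nanoparticle
    Concentrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates and optimally controls the transport of
    superparamagnetic nanoparticle concentrations in a two-dimensional
    fluid sample surrounded by electromagnets, for magnetic drug
    targeting studies. Computes circular-coil magnetic fields and their
    analytic gradients via complete elliptic integrals, the Langevin
    magnetization and magnetic force on single-domain particles, and the
    resulting Stokes drift. Discretizes the advection-diffusion equation
    on a voxel grid into a linear state-space system with no-flux
    boundaries and integrates it with fourth-order Runge-Kutta. Reduces
    the state dimension by snapshot proper orthogonal decomposition and
    optimizes piecewise-constant coil currents by direct multiple
    shooting, alternating reduction and optimization to maximize the
    particle concentration in target voxels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
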