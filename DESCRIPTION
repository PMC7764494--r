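Package: ionperm
Title: Ion Permeation and Selectivity Analysis from Equilibrium Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimators for ion permeation and selectivity in narrow channels
    from equilibrium trajectories: axial potential of mean force by Boltzmann
    inversion of ion density, selectivity-filter occupancy traces, axially
    binned coordination-number profiles, and linear-response conductance via
    the collective diffusion model (charge displacement mean-square analysis).
    Includes a binomial population model for random heterotetramer assembly
    from monomer mixtures, an overdamped Langevin (Brownian dynamics)
    generator of multi-ion trajectories in one-dimensional channel-like
    potentials with known ground truth, and a plain-text columnar trajectory
    format with periodic-boundary unwrapping.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
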