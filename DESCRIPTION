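Package: cavityfield
Title: Long-Range Electrostatic Potential and Field Mapping of Chaperonin Cavities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Maps the time-averaged long-range (reciprocal-space particle-mesh
    Ewald) electrostatic potential of a charged molecular assembly on a periodic
    grid, isolates a barrel cavity with a maximal inscribed axis-aligned
    ellipsoid found by geometric inversion, filters grid points by the temporal
    standard deviation of the potential, fits linear and quadratic polynomial
    potential models to the surviving control points by least squares, and
    derives the resultant electric field, including export of a constant-field
    keyword for molecular dynamics engines. Ships a synthetic-data module
    (jittered charged barrels with planted axial fields, noisy polynomial
    grids) so every stage is testable without external trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    bio3d,
    optparse,
    patchwork,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
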