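Package: bombusim
Title: Spatially Explicit Simulation of Bumble Bee Populations and
    Pollination Services in Agricultural Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A process-based, spatially explicit model of central-place
    foraging bees (parameterized for common early-active bumble bees) on
    categorical land-use rasters. Flower visitation rates follow a
    resource-weighted, distance-discounted allocation of foragers with
    truncated exponential kernels; within-season colony growth (workers,
    then new queens) is driven by collected resources through a
    saturating lognormal-CDF production function; between seasons new
    queens disperse, settle under density dependence, and colony numbers
    are realized by Poisson draws. The package includes generators for
    synthetic agricultural landscape rotations (field blocks, crop
    rotation, field-edge rasters), agri-environment management scenarios
    (widened grassy field margins, annually re-sown late-flowering
    flower strips), a multi-year simulation driver with burn-in, and
    buffer-aggregated response series for ecosystem-service assessment.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
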