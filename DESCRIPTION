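Package: votsim
Title: Lumped-Parameter Hemodynamics of Ventricular Outflow Tract Obstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop lumped-parameter (0D) simulation of the complete
    cardiovascular circulation coupled to a one-dimensional orifice-loss model
    of a right or left ventricular outflow tract (RVOT/LVOT) obstruction.
    Ships a frozen parameterization for a reference 2-year-old child, computes
    clinical hemodynamic indices (cardiac output, arterial pressures, mean and
    peak trans-obstruction gradient, Doppler simplified-Bernoulli gradient),
    and runs obstruction-severity sweeps relating narrowing ratio to pressure
    gradient and cardiac output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
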