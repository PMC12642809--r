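Package: pdmsdose
Title: Partition-Diffusion Modelling of Hydrophobic-Chemical Loss into PDMS
        Microdevices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and inference tools for quantifying how hydrophobic
    small molecules (steroid hormones in particular) are absorbed by
    polydimethylsiloxane (PDMS) in microfluidic cell-culture devices.
    Implements a partition-diffusion transport model with interfacial
    mass-transfer boundary conditions; a finite-volume forward model of
    two-chamber diffusion-through-membrane experiments; least-squares
    estimation of partition coefficients, diffusivities and the interfacial
    mass-transfer coefficient from concentration time series, with log-linear
    cosolvent extrapolation to aqueous partition coefficients; and a reduced
    2-D solver for static and perfused microchannels embedded in PDMS slabs
    under pulse and circadian dosing, reporting delivered-mass dose-fidelity
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    knitr
Config/testthat/edition: 3
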