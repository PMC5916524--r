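Package: spportraits
Title: Stochastic Phase Portraits for Chemical Reaction Networks
Version: 0.1.0
Authors@R:
    person("spportraits", "developers", email = "spportraits@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse intrinsic noise in chemical reaction networks
    through stochastic phase portraits. From a reaction specification the
    package constructs the Fokker-Planck drift vector, diffusion matrix and
    convective field on concentration space, locates and classifies fixed
    points of the convective field (candidate maxima and minima of the
    stationary probability density), extracts nullclines, integrates
    convective trajectories and detects limit cycles, and locates stochastic
    (phenomenological) bifurcations under parameter or system-size variation,
    including the nullcline-gap bifurcation that creates boundary maxima.
    Predictions can be cross-checked with an exact Gillespie stochastic
    simulation and, for one-dimensional or conservation-reduced systems, with
    the closed-form stationary density. Built-in model fixtures cover a
    collective-foraging (ant recruitment) model and the Rosenzweig-MacArthur
    predator-prey model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
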