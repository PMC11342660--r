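Package: forestmit
Title: Factorial Assessment of the Carbon Mitigation Potential of Managed Forests
Version: 0.1.0
Authors@R: person("forestmit", "maintainers", email = "forestmit@example.org", role = c("aut", "cre"))
Description: A reduced-form, patch-replicated forest stand simulator coupled to
    harvested-wood-product accounting for quantifying the carbon mitigation
    potential of managed temperate forests. The package enumerates a factorial
    design over climate scenario, disturbance response, forest age and type,
    harvest intensity, salvage logging, wood usage, cascading, and
    decarbonization pace; simulates stand carbon pools under stochastic
    stand-replacing disturbances; partitions harvested carbon into products,
    firewood and residues; decays product pools with Gamma survival curves;
    credits material and fuel substitution with time-declining displacement
    factors; and attributes effects with pairwise differences between partner
    simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
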