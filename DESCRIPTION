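Package: netaging
Title: Gene Network Reliability Models of Cellular Aging
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits and simulates a parsimonious gene-network reliability model
    of cellular aging for replicative lifespan data. The model builds a cell
    from non-aging parts: each of m essential modules holds n gene
    interactions whose strength decays exponentially at rate lambda, with
    binomial activation probability p at birth. The emergent network hazard
    R*(1 + t/t0)^(n-1) extends the two-parameter Gompertz model and is fitted
    to per-cell lifespans by maximum likelihood, with bootstrap uncertainty
    and AIC comparison against Gompertz and Weibull alternatives. Includes
    exact inverse-CDF and mechanistic cell-by-cell simulators, empirical
    hazard diagnostics, and cross-strain analyses (Strehler-Mildvan
    correlation, mediation test, interaction decay-time summaries) over
    fitted strain parameter tables, with a bundled table for 15 wild yeast
    isolates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
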