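Package: selfthin
Title: Self-Thinning Boundary Lines for Mixed Forest Stands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates maximum size-density (self-thinning) boundary lines for
    mixed forest stands from plot-level inventory tables. Implements a variable
    density model driven by quadratic mean diameter and dominant height
    alongside Reineke's classical diameter-only model, fitted either by linear
    quantile regression at upper quantiles or by stochastic frontier maximum
    likelihood with normal-half-normal, normal-exponential, and
    normal-truncated-normal composed errors. Provides stand density index
    projection to a reference tree size, relative-density and
    mortality-density diagnostics, traditional boundary-point selection
    methods (equal-width interval, mortality threshold, relative density,
    upper convex hull), stand-structure covariate models built on Shannon and
    Simpson diversity indices, and a synthetic stand generator for method
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
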