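Package: lakesar
Title: Multimodel Island Species-Area Analysis for Postglacial Lake Fish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for island species-area relationship (ISAR) analysis of
    lake archipelagos: a configurable catalogue of species-area model forms
    (power, asymptotic, sigmoid and piecewise threshold models) fitted by
    Poisson maximum likelihood with multi-start optimisation and ranked by
    AICc and Akaike weights; community scenarios separating the pre-1900
    native fauna from human-modified communities (introductions,
    translocations, extirpations); a passive-sampling (rarefaction) null
    model; a stochastic colonisation-speciation-extinction simulator of ISAR
    emergence through time; and a synthetic-data generator emulating the
    statistical structure of peri-Alpine lake fish communities so the whole
    pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
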