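Package: commsteady
Title: Steady-State Solutions of Microbial Community Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Finds metabolically stationary states of microbial community
    metabolic models in chemostat and steady-state batch environments,
    under distributed (rational agent) or centralized (rational community)
    decision making. Implements Karush-Kuhn-Tucker complementarity
    reformulations of the four model variants, a two-stage numerical
    scheme (abundance-grid big-M mixed-integer search followed by
    Levenberg-Marquardt refinement), and an exact active-set enumeration
    solver for small networks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: jsonlite, minpack.lm, Rcpp, stats, utils, xml2, yaml
LinkingTo: Rcpp
Suggests: boot, optparse, testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
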