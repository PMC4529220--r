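Package: parietoreach
Title: Evolved Parietal-Cortex Network Models of Visually and Memory Guided Reaching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates recurrent rate-network models of the posterior parietal
    cortex (PPC) performing center-out reaching under realistic visual and
    proprioceptive delays. Four architectures (feedforward, feedback, lateral,
    feedback-lateral) are optimized with a (mu, lambda) evolution strategy on a
    visually guided task and tested on a memory guided task. Includes
    population-vector motor decoding, an analytic optimal-fitness oracle,
    connectivity and direction-selectivity analyses, velocity-profile
    diagnostics, and deterministic experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
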