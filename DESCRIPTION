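Package: asterdrift
Title: Models of Centripetal MTOC Motility in Mouse Oocyte Meiosis I
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis tools for the centripetal transport of
    microtubule organizing centers (MTOCs) during acentrosomal spindle
    assembly in mouse oocyte meiosis I. Implements a phenomenological random
    walk in a radially symmetric drift field with absorbing chromatin, a
    weighted-error rank-minimization scheme for fitting the drift-field shape
    to trajectory statistics, a simplified two-dimensional microtubule-motor
    Langevin engine (dynamic-instability filaments, surface-immobilized
    minus-end-directed motors with Kramers force-dependent detachment, and
    diffusible cross-linking motor complexes), trajectory motility statistics
    (mean squared displacement fits, directionality, capture times, Hill-type
    distance-time fits), and a synthetic-data generator emulating sparse
    particle-tracking experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    minpack.lm,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    withr,
    optparse
Config/testthat/edition: 3
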