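Package: xmodal
Title: Cross-Modal Generalization Analysis for Visuo-Tactile Cortical Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying visuo-tactile cross-modal generalization in
    mouse dorsal cortex. Implements a four-area recurrent excitatory/inhibitory
    rate-network model of generalized sensorimotor learning with drift-diffusion
    decisions and reward-modulated Hebbian plasticity; Go/No-go behavioral
    performance metrics; single-neuron sparse-noise analyses (responsivity,
    functional cell classes, max-model multisensory indices, Bayesian
    cross-modal population decoding); wide-field topographic map statistics;
    and seeded synthetic-data generators with known ground truth for all of the
    above.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
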