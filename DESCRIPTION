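Package: visroutines
Title: Recurrent Networks That Learn Multi-Step Visual Routines with a
    Biologically Plausible Reinforcement-Learning Rule
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulator and analysis toolkit for gated recurrent
    convolutional networks that learn visual routines (curve tracing,
    search-then-trace, trace-then-search) on a pixel grid by trial and
    error. Networks relax to a fixed point, select eye-movement targets
    from Q-values, and learn with RELEARNN, a four-factor Hebbian rule in
    which a reward-prediction error gates plasticity together with a
    credit-assignment signal propagated through an accessory network with
    transposed weights (Almeida-Pineda style recurrent learning).
    Includes synthetic stimulus generators, staged curricula, and
    neurophysiology-style analyses of response modulation (modulation
    index, modulation latency, minimal processing timesteps,
    generalization to longer curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
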