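Package: boltzcode
Title: Thermodynamics of Stochastic Population Codes in Restricted Boltzmann Machines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study optimal encoding in stochastic binary latent-variable
    models of neural population coding. Generates synthetic binary stimuli (2D
    Ising lattice configurations sampled by Swendsen-Wang or Metropolis dynamics,
    and median-binarized correlated textures), trains restricted Boltzmann
    machines with one-step contrastive divergence, and computes the
    information-theoretic and thermodynamic quantities of the trained code:
    stimulus-conditioned hidden-layer entropy in closed form, codeword energies,
    visible free energies, the Fisher information matrix and its spectrum over an
    inverse-temperature sweep, stimulus-energy binned energy-entropy profiles,
    and Zipf rank-frequency statistics. Designed to quantify stimulus-dependent
    variability suppression and the emergence of statistical criticality (a 1:1
    energy-entropy trade-off) above a critical hidden-layer size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
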