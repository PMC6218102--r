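Package: cloneburst
Title: Bursty Clonal Dynamics and Disappearance Statistics for
    Hematopoietic Clone Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Neutral multi-compartment model of clonal hematopoiesis for
    barcoded clone-tracking time series: stochastic stem-cell self-renewal
    giving a geometric clone-size law, generation-limited progenitor bursts
    triggered by Poisson differentiation events, peripheral granulocyte
    turnover, and small-fraction binomial blood sampling.  Implements the
    clone-disappearance statistic Y_z (mean abundance conditioned on the
    number of samples in which a clone is absent) and simulation-based
    least-squares inference of the effective maximum progenitor generation
    L_e and the total tagged stem-cell differentiation rate, together with
    leave-out and abundance-threshold robustness analyses, a sampling-only
    null model, and a synthetic data generator emulating rhesus macaque
    clone-tracking experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
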