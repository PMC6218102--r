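#' Published least-squares fits for the three macaque datasets
#'
#' Reference values of the effective generation `L_e*`, the tagged
#' differentiation rate `A_ss_plus*` (events/day), the whole-animal rate
#' `A_ss*`, and the experimental design summaries for the three rhesus
#' macaque granulocyte clone-tracking datasets the model was fitted to.
#' Useful for consistency checks: `A_ss* = A_ss_plus* / egfp_fraction`,
#' and `A_ss_plus*` matches the steady-state balance
#' `M_ss * egfp_fraction * mu_m * 2^(-L_e*)` within the rounding of the
#' printed `L_e*`.  Reproducing these numbers from raw data requires the
#' original experiment's supplemental clone-abundance tables, which are
#' not bundled here.
#'
#' @return A data.frame with one row per animal.
#' @export
reference_fits <- function() {
  data.frame(
    animal = c("RQ5427", "2RC003", "RQ3570"),
    n_clones = c(536L, 1371L, 442L),
    months_followed = c(67, 103, 38),
    L_e_star = c(23.4, 25.0, 24.0),
    A_ss_plus_star = c(14.7, 6.7, 19.3),
    A_ss_star = c(282.7, 136.7, 224.4),
    M_ss = c(3.2e9, 4.6e9, 3.8e9),
    egfp_fraction = c(0.052, 0.049, 0.086),
    mu_m = 1
  )
}
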