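#' Specification for a synthetic clone-tracking dataset
#'
#' Bundles ground-truth model parameters with an experiment-design
#' template emulating the rhesus macaque clone-tracking studies: a few
#' hundred to a thousand clones, 4--12 samples at 5--11 month gaps,
#' thousands of tagged cells per sample out of a tagged pool of order
#' 1e8, giving sampling fractions of 1e-5 to 1e-3.
#'
#' @param lam,C_h,r_n,L_e Ground-truth effective model parameters.
#' @param t_months Sampling times (months); the default mirrors an
#'   8-retained-sample design over ~5 years (plus an early month-2
#'   sample that the statistics exclude by default).
#' @param S_plus_range Range from which per-sample tagged cell counts
#'   are drawn uniformly.
#' @param M_ss_plus Tagged peripheral granulocyte pool (cells).
#' @param egfp_fraction Tagged fraction among all granulocytes.
#' @param seed Master seed for the whole generation.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(lam = 0.99, C_h = 500, r_n = 2.5, L_e = 23.4,
                           t_months = c(2, 8, 14, 25, 33, 43, 50, 60, 67),
                           S_plus_range = c(5e3, 3e4),
                           M_ss_plus = 1.664e8, egfp_fraction = 0.052,
                           seed = 1L) {
  stopifnot(length(t_months) >= 4, all(diff(t_months) > 0),
            length(S_plus_range) == 2, S_plus_range[1] <= S_plus_range[2])
  eps_range <- S_plus_range / M_ss_plus
  if (eps_range[1] < 1e-5 || eps_range[2] > 1e-3) {
    stop("design implies sampling fractions outside [1e-5, 1e-3]")
  }
  hsc_clone_law(lam, C_h)  # validate
  structure(list(lam = lam, C_h = C_h, r_n = r_n, L_e = L_e,
                 t_months = t_months, S_plus_range = S_plus_range,
                 M_ss_plus = M_ss_plus, egfp_fraction = egfp_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a complete synthetic clone-tracking dataset
#'
#' Runs the full forward model at known ground truth: draw a clone-size
#' configuration from the geometric law, simulate bursty peripheral
#' trajectories, and sample blood at the design times.  The returned
#' truth record carries everything needed to regenerate the dataset
#' bit-for-bit.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `ab` (the `abundance_matrix`), `truth` (spec,
#'   drawn `S_plus`, the configuration, and derived `A_ss_plus`), and
#'   `trajs` (the underlying `clone_trajectories`).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(substream_seed(spec$seed, 101L))
  S_plus <- round(stats::runif(length(spec$t_months),
                               spec$S_plus_range[1], spec$S_plus_range[2]))
  design <- experiment_design(spec$t_months, S_plus, spec$M_ss_plus,
                              spec$egfp_fraction)
  params <- effective_params(lam = spec$lam, C_h = spec$C_h,
                             r_n = spec$r_n, L_e = spec$L_e,
                             M_ss_plus = spec$M_ss_plus)
  config <- draw_hsc_config(hsc_clone_law(spec$lam, spec$C_h),
                            seed = substream_seed(spec$seed, 102L))
  trajs <- simulate_clones(config, params, design,
                           seed = substream_seed(spec$seed, 103L))
  ab <- sample_blood(trajs, seed = substream_seed(spec$seed, 104L))
  if (all(ab$counts == 0)) {
    stop("degenerate synthetic spec: no clone was ever detected")
  }
  list(ab = ab,
       truth = list(spec = spec, S_plus = S_plus, config = config,
                    A_ss_plus = params$A_ss_plus),
       trajs = trajs)
}

#' Tiny hand-checkable fixtures for the statistics pipeline
#'
#' Small abundance matrices (at most a handful of clones and samples)
#' whose summary statistics can be verified by hand: `four_clones` with
#' absence counts (0, 1, 2, 4) where the all-absent clone is dropped,
#' `two_bins` with two clones sharing one absence bin, and `empty_bin`
#' exercising the Y_z = 0 convention for unpopulated bins.
#'
#' @return A named list of `abundance_matrix` objects.
#' @export
fixture_library <- function() {
  mk <- function(counts, S_plus, t_months = seq(10, by = 8,
                                                length.out = ncol(counts)),
                 M = 1e6) {
    design <- experiment_design(t_months, S_plus, M)
    new_abundance_matrix(counts, sweep(counts, 2, S_plus, "/"), design)
  }
  four <- rbind(clone1 = c(10, 10, 10, 10),
                clone2 = c(0, 20, 20, 20),
                clone3 = c(0, 5, 0, 5),
                clone4 = c(0, 0, 0, 0))
  two <- rbind(a = c(10, 0, 10, 20),
               b = c(30, 10, 0, 0),
               c = c(0, 30, 10, 0))
  empt <- rbind(big = c(50, 50, 50),
                small = c(0, 10, 0))
  list(four_clones = mk(four, S_plus = 100),
       two_bins = mk(two, S_plus = 100),
       empty_bin = mk(empt, S_plus = 100))
}
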