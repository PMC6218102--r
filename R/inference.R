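#' Specification of a simulation-based least-squares fit
#'
#' Defines the grid over the effective generation `L_e` (and optionally
#' the division rate `r_n`), the fixed clone-size law, the number of
#' forward-simulation replicates per grid point, and the clone-size
#' configuration policy.
#'
#' @param Le_grid Grid of effective generations (default 19..28 in steps
#'   of 0.2, the biologically plausible range at a resolution finer than
#'   the reported uncertainty of the estimate).
#' @param r_n Progenitor division rate(s); a single value for 1-D fits,
#'   a vector for 2-D surfaces.  Values in \[0.01, 10\].
#' @param lam,C_h Clone-size law used when drawing configurations.
#' @param n_replicates Independent forward simulations per grid point
#'   (200 for production fits; >= 25 for desk-scale work).
#' @param seed Master seed; everything downstream is derived from it.
#' @param h_policy `"draw"` redraws a configuration from the geometric
#'   law for each replicate; `"proportional"` fixes `h_i` proportional to
#'   the observed mean abundances.
#' @param H_plus_target Tagged HSC pool used to scale proportional
#'   configurations (cells).
#' @param y_threshold Minimum mean abundance; clones below it are removed
#'   from the data and from every simulated replicate before computing
#'   `Y_z`.
#' @param exclude Sample-exclusion rule passed to [clone_summaries()].
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(Le_grid = seq(19, 28, by = 0.2), r_n = 2.5,
                     lam = 0.99, C_h = 500, n_replicates = 200,
                     seed = 1L, h_policy = c("draw", "proportional"),
                     H_plus_target = 1e4, y_threshold = 0,
                     exclude = "auto") {
  h_policy <- match.arg(h_policy)
  stopifnot(all(Le_grid > 0), all(r_n > 0), n_replicates >= 1,
            y_threshold >= 0)
  if (any(Le_grid < 19 - 1e-9) || any(Le_grid > 28 + 1e-9)) {
    warning("Le_grid extends outside the default biological range [19, 28]")
  }
  if (any(r_n < 0.01) || any(r_n > 10)) {
    warning("r_n outside the default biological range [0.01, 10]")
  }
  hsc_clone_law(lam, C_h)  # validate
  structure(list(Le_grid = sort(Le_grid), r_n = r_n, lam = lam, C_h = C_h,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), h_policy = h_policy,
                 H_plus_target = H_plus_target,
                 y_threshold = y_threshold, exclude = exclude),
            class = "fit_spec")
}

# Y_z from per-clone (y, z) after an abundance threshold.
thresholded_Y <- function(y, z, J, threshold) {
  keep <- y >= threshold
  if (!any(keep)) return(NULL)
  conditional_mean_Yz(y[keep], z[keep], J)
}

# One forward replicate: configuration -> trajectories -> blood sample ->
# Y_z vector (zeros if nothing is detected).
simulate_Y_once <- function(params, design, kernel, spec, rep_seed,
                            fixed_config = NULL) {
  config <- if (is.null(fixed_config)) {
    draw_hsc_config(hsc_clone_law(spec$lam, spec$C_h),
                    seed = substream_seed(rep_seed, 1L))
  } else fixed_config
  trajs <- simulate_clones(config, params, design,
                           seed = substream_seed(rep_seed, 2L),
                           kernel = kernel)
  ab <- sample_blood(trajs, seed = substream_seed(rep_seed, 3L))
  f <- ab$fractions
  detected <- rowSums(f) > 0
  J <- ncol(f)
  if (!any(detected)) return(numeric(J))
  f <- f[detected, , drop = FALSE]
  y <- rowMeans(f)
  z <- rowSums(f == 0)
  res <- thresholded_Y(y, z, J, spec$y_threshold)
  if (is.null(res)) numeric(J) else res$Y
}

#' Fit the effective generation by simulated least squares
#'
#' Implements the forward-simulation workflow: from the observed
#' abundance matrix, extract the disappearance statistic `Y_hat_z`; for
#' every grid point `(r_n, L_e)`, run `n_replicates` independent
#' pipelines (draw a clone-size configuration, simulate bursty clone
#' trajectories, sample blood, compute `Y_z`); average the replicate
#' `Y_z` per bin and score the squared-error objective against
#' `Y_hat_z`; return the grid minimum.  Ties are broken toward the
#' smaller `L_e` (the conservative, lower-amplification estimate).  The
#' total tagged differentiation rate at the optimum follows from the
#' steady-state balance.
#'
#' @param ab_hat Observed `abundance_matrix`.
#' @param spec A [fit_spec()].
#' @return An object of class `fit_result`: data.frame `grid` with
#'   `r_n`, `L_e`, `mse_mean`, `mse_sd`, the optimum (`L_e_star`,
#'   `r_n_star`, `A_ss_plus_star`), observed `Y_hat`, mean simulated
#'   `Y_star` at the optimum, and bookkeeping (`J`, seeds, clone counts).
#' @export
fit_lse <- function(ab_hat, spec) {
  stopifnot(inherits(ab_hat, "abundance_matrix"), inherits(spec, "fit_spec"))
  s_hat <- clone_summaries(ab_hat, spec$exclude)
  data_Y <- thresholded_Y(s_hat$y, s_hat$z, s_hat$J, spec$y_threshold)
  if (is.null(data_Y)) stop("abundance threshold removed every clone")
  Y_hat <- data_Y$Y
  J <- s_hat$J
  design <- subset_design(ab_hat$design, s_hat$kept_samples)

  fixed_config <- NULL
  if (spec$h_policy == "proportional") {
    fixed_config <- config_from_abundance(s_hat$y, spec$H_plus_target)
  }

  grid <- expand.grid(L_e = spec$Le_grid, r_n = spec$r_n,
                      KEEP.OUT.ATTRS = FALSE)[, c("r_n", "L_e")]
  mse_mean <- mse_sd <- numeric(nrow(grid))
  Y_mean <- matrix(0, nrow(grid), J)
  for (g in seq_len(nrow(grid))) {
    params <- effective_params(lam = spec$lam, C_h = spec$C_h,
                               r_n = grid$r_n[g], L_e = grid$L_e[g],
                               M_ss_plus = design$M_ss_plus)
    kernel <- burst_kernel(params$prog)
    Yrep <- matrix(0, spec$n_replicates, J)
    for (r in seq_len(spec$n_replicates)) {
      rep_seed <- substream_seed(spec$seed, g * 131071L + r)
      Yrep[r, ] <- simulate_Y_once(params, design, kernel, spec, rep_seed,
                                   fixed_config)
    }
    Y_mean[g, ] <- colMeans(Yrep)
    mse_mean[g] <- mse_objective(Y_mean[g, ], Y_hat)
    mse_sd[g] <- stats::sd(apply(Yrep, 1, mse_objective, Y_hat = Y_hat))
  }
  if (all(Y_mean[, -1] == 0)) {
    stop("all simulated Y bins (z >= 1) are empty; fit aborted ",
         "(check design, C_h, and threshold)")
  }
  grid$mse_mean <- mse_mean
  grid$mse_sd <- mse_sd
  # grid rows are ordered by increasing L_e within r_n, so which.min
  # already breaks exact ties toward the smaller L_e
  best <- which.min(mse_mean)
  structure(list(grid = grid,
                 L_e_star = grid$L_e[best], r_n_star = grid$r_n[best],
                 A_ss_plus_star = ass_plus_from_Le(design$M_ss_plus, 1,
                                                   grid$L_e[best]),
                 Y_hat = Y_hat, Y_star = Y_mean[best, ],
                 Y_mean = Y_mean, J = J,
                 n_clones_data = length(s_hat$y),
                 n_clones_retained = sum(s_hat$y >= spec$y_threshold),
                 spec = spec),
            class = "fit_result")
}

subset_design <- function(design, keep_j) {
  experiment_design(design$t_months[keep_j], design$S_plus[keep_j],
                    design$M_ss_plus, design$egfp_fraction)
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> L_e* = ", x$L_e_star, ", r_n* = ", x$r_n_star,
      ", A_ss+* = ", format(x$A_ss_plus_star, digits = 3),
      "/day (min MSE = ", format(min(x$grid$mse_mean), digits = 3),
      " over ", nrow(x$grid), " grid points, ",
      x$spec$n_replicates, " replicates each)\n", sep = "")
  invisible(x)
}

#' Mean squared-error surface over (r_n, L_e)
#'
#' Runs the same replicate machinery as [fit_lse()] on a 2-D grid and
#' returns the grid with the natural log of the mean MSE for surface
#' visualization.
#'
#' @inheritParams fit_lse
#' @return The [fit_lse()] result with an extra `log_mse` column in
#'   `$grid`.
#' @export
mse_surface <- function(ab_hat, spec) {
  if (length(spec$r_n) < 2) {
    warning("mse_surface called with a single r_n value; surface is 1-D")
  }
  fit <- fit_lse(ab_hat, spec)
  fit$grid$log_mse <- log(fit$grid$mse_mean)
  fit
}

#' Refit on truncated time series (leave-out robustness)
#'
#' Repeats the fit using only the first `j` sampling times of the raw
#' abundance matrix, for each requested `j`, to check the stability of
#' the `L_e` estimate against shortened follow-up.
#'
#' @inheritParams fit_lse
#' @param keep_first_j Integer vector of truncation lengths (each >= 2
#'   raw samples).
#' @return A list with `summary` (data.frame of `j`, `L_e_star`,
#'   `A_ss_plus_star`, `mse_min`) and `fits` (the per-truncation
#'   `fit_result`s).
#' @export
robustness_leave_out <- function(ab_hat, spec, keep_first_j) {
  stopifnot(all(keep_first_j >= 2),
            all(keep_first_j <= ncol(ab_hat$fractions)))
  fits <- lapply(keep_first_j, function(j) {
    keep <- seq_len(j)
    ab_j <- new_abundance_matrix(
      ab_hat$counts[, keep, drop = FALSE],
      ab_hat$fractions[, keep, drop = FALSE],
      subset_design(ab_hat$design, keep))
    fit_lse(ab_j, spec)
  })
  summary <- data.frame(
    j = keep_first_j,
    L_e_star = vapply(fits, `[[`, numeric(1), "L_e_star"),
    A_ss_plus_star = vapply(fits, `[[`, numeric(1), "A_ss_plus_star"),
    mse_min = vapply(fits, function(f) min(f$grid$mse_mean), numeric(1)))
  list(summary = summary, fits = fits)
}

#' Refit under abundance thresholds (threshold robustness)
#'
#' Removes clones whose mean abundance falls below each threshold --
#' symmetrically from the data and from every simulated replicate -- and
#' refits, to check that the estimate does not depend on the smallest
#' clones.
#'
#' @inheritParams fit_lse
#' @param y_thresholds Non-negative abundance thresholds.
#' @return A list with `summary` (data.frame of `threshold`,
#'   `n_retained`, `L_e_star`, `mse_min`) and `fits`.
#' @export
robustness_threshold <- function(ab_hat, spec, y_thresholds) {
  stopifnot(all(y_thresholds >= 0))
  fits <- lapply(y_thresholds, function(thr) {
    sp <- spec
    sp$y_threshold <- thr
    fit_lse(ab_hat, sp)
  })
  summary <- data.frame(
    threshold = y_thresholds,
    n_retained = vapply(fits, `[[`, numeric(1), "n_clones_retained"),
    L_e_star = vapply(fits, `[[`, numeric(1), "L_e_star"),
    mse_min = vapply(fits, function(f) min(f$grid$mse_mean), numeric(1)))
  list(summary = summary, fits = fits)
}
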