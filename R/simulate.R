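DAYS_PER_MONTH <- 30.4

#' Convert sampling times between months and days
#'
#' Months are the canonical external unit (as in clone-tracking data
#' tables); internal dynamics run in days.  One month is taken as 30.4
#' days, applied once at the I/O boundary.
#'
#' @param months,days Numeric times.
#' @return Converted times.
#' @export
months_to_days <- function(months) months * DAYS_PER_MONTH

#' @rdname months_to_days
#' @export
days_to_months <- function(days) days / DAYS_PER_MONTH

#' Blood sampling design of a clone-tracking experiment
#'
#' @param t_months Sampling times in months, strictly increasing,
#'   length >= 2.
#' @param S_plus Number of tagged sampled cells per sample (recycled to
#'   `length(t_months)`).
#' @param M_ss_plus Steady-state tagged peripheral granulocyte pool
#'   (cells).
#' @param egfp_fraction Optional tagged fraction among all granulocytes.
#' @return An object of class `experiment_design` with sampling fractions
#'   `eps = S_plus / M_ss_plus`.
#' @export
experiment_design <- function(t_months, S_plus, M_ss_plus,
                              egfp_fraction = NULL) {
  if (length(t_months) < 2) stop("need at least 2 sampling times")
  if (any(diff(t_months) <= 0)) stop("t_months must be strictly increasing")
  S_plus <- rep_len(S_plus, length(t_months))
  if (any(S_plus < 1)) stop("S_plus must be at least 1")
  stopifnot(M_ss_plus > 0)
  eps <- S_plus / M_ss_plus
  if (any(eps <= 0 | eps >= 1)) stop("sampling fractions must lie in (0,1)")
  if (!is.null(egfp_fraction)) {
    stopifnot(egfp_fraction > 0, egfp_fraction <= 1)
  }
  structure(list(t_months = t_months, S_plus = S_plus,
                 M_ss_plus = M_ss_plus, egfp_fraction = egfp_fraction,
                 eps = eps),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design> J = ", length(x$t_months), " samples, months ",
      x$t_months[1], "-", x$t_months[length(x$t_months)],
      ", eps = ", format(min(x$eps), digits = 2), "-",
      format(max(x$eps), digits = 2), "\n", sep = "")
  invisible(x)
}

#' Effective model parameters for clone-trajectory simulation
#'
#' The four free parameters of the reduced model -- clone-size shape
#' `lam`, clone count `C_h`, progenitor division rate `r_n` and effective
#' generation `L_e` -- plus the fixed downstream rates.  The total tagged
#' differentiation rate is pinned by the steady-state balance
#' `A_ss_plus = M_ss_plus * mu_m * 2^(-L_e)` unless overridden.
#'
#' @param lam Geometric clone-size shape factor in \[0, 1).
#' @param C_h Number of tagged HSC clones.
#' @param r_n Progenitor division rate (1/day).
#' @param L_e Effective maximum progenitor generation.
#' @param M_ss_plus Tagged peripheral pool used in the balance constraint
#'   (cells); may be omitted when `A_ss_plus` is given directly.
#' @param omega,mu_m Fixed maturation and granulocyte death rates (1/day).
#' @param A_ss_plus Optional explicit total tagged differentiation rate
#'   (events/day).
#' @return An object of class `effective_params`.
#' @export
effective_params <- function(lam = 0.99, C_h = 500, r_n = 2.5, L_e = 23.4,
                             M_ss_plus = NULL, omega = 0.16, mu_m = 1,
                             A_ss_plus = NULL) {
  if (is.null(A_ss_plus)) {
    if (is.null(M_ss_plus)) stop("supply M_ss_plus or A_ss_plus")
    A_ss_plus <- ass_plus_from_Le(M_ss_plus, mu_m, L_e)
  }
  law <- hsc_clone_law(lam, C_h)   # validates lam, C_h
  prog <- progenitor_rates(r_n = r_n, L = L_e, mu_n = 0, mu_nL = 0,
                           omega = omega, mu_m = mu_m)
  structure(list(lam = law$lam, C_h = law$C_h, r_n = r_n, L_e = L_e,
                 omega = omega, mu_m = mu_m, A_ss_plus = A_ss_plus,
                 prog = prog),
            class = "effective_params")
}

#' @export
print.effective_params <- function(x, ...) {
  cat("<effective_params> lam = ", x$lam, ", C_h = ", x$C_h,
      ", r_n = ", x$r_n, ", L_e = ", x$L_e,
      ", A_ss+ = ", format(x$A_ss_plus, digits = 4), "/day\n", sep = "")
  invisible(x)
}

#' Simulate peripheral granulocyte trajectories of tagged clones
#'
#' Each clone `i` fires HSC differentiation events as a homogeneous
#' Poisson process with rate `alpha * h_i`, where
#' `alpha = A_ss_plus / sum(h)`.  Every event launches a deterministic
#' granulocyte burst `m_b(t - tau_k)`; the clone's peripheral population
#' at each sampling time is the shot-noise superposition of all bursts
#' still in flight.  Events start a warm-up window before the first
#' sample so the process is stationary when observation begins.
#'
#' @param config An `hsc_config` of clone sizes.
#' @param params An [effective_params()].
#' @param design An [experiment_design()].
#' @param seed Master seed; per-clone sub-streams keep draws independent
#'   of `C_h`.
#' @param kernel Optional precomputed [burst_kernel()] (must match
#'   `params`); computed on the fly otherwise.
#' @param t_warm Warm-up window before the first sample (days); defaults
#'   to the kernel support.
#' @param keep_events If `TRUE`, the per-clone differentiation times are
#'   returned in `events`.
#' @return An object of class `clone_trajectories`: list with matrix `m`
#'   (clones x samples, cells), `n_events` per clone, the `design`, and
#'   optionally `events`.
#' @export
simulate_clones <- function(config, params, design, seed, kernel = NULL,
                            t_warm = NULL, keep_events = FALSE) {
  stopifnot(inherits(config, "hsc_config"),
            inherits(params, "effective_params"),
            inherits(design, "experiment_design"))
  if (is.null(kernel)) kernel <- burst_kernel(params$prog)
  support <- max(kernel$times)
  if (is.null(t_warm)) t_warm <- support
  if (t_warm < support) {
    warning("t_warm shorter than kernel support; early samples biased low")
  }
  t_days <- months_to_days(design$t_months)
  t0 <- t_days[1] - t_warm
  window <- t_days[length(t_days)] - t0
  alpha <- params$A_ss_plus / config$H_plus
  rate <- alpha * config$h
  C <- length(config$h)

  n_events <- integer(C)
  ev_clone <- vector("list", C)
  for (i in seq_len(C)) {
    set.seed(substream_seed(seed, i))
    k <- stats::rpois(1, rate[i] * window)
    n_events[i] <- k
    if (k > 0) ev_clone[[i]] <- t0 + stats::runif(k) * window
  }
  tau <- unlist(ev_clone, use.names = FALSE)
  clone_of <- rep.int(seq_len(C), n_events)

  m <- matrix(0, C, length(t_days))
  if (length(tau)) {
    for (j in seq_along(t_days)) {
      lag <- t_days[j] - tau
      sel <- lag >= 0 & lag <= support
      if (!any(sel)) next
      contrib <- stats::approx(kernel$times, kernel$m_b, lag[sel],
                               rule = 2)$y
      keep <- contrib >= 1       # sub-cell burst tails are dropped
      if (!any(keep)) next
      agg <- rowsum(contrib[keep], clone_of[sel][keep])
      m[as.integer(rownames(agg)), j] <-
        m[as.integer(rownames(agg)), j] + agg[, 1]
    }
  }
  dimnames(m) <- list(paste0("clone", seq_len(C)), design$t_months)
  structure(list(m = m, n_events = n_events, design = design,
                 events = if (keep_events) ev_clone),
            class = "clone_trajectories")
}

#' Total tagged peripheral pool across clones
#'
#' @param trajs A `clone_trajectories` object.
#' @return Numeric vector `M_plus(t_j)` of column sums (cells).
#' @export
aggregate_pool <- function(trajs) {
  stopifnot(inherits(trajs, "clone_trajectories"))
  colSums(trajs$m)
}
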