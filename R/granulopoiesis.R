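#' Transit-amplifying progenitor and granulocyte rate parameters
#'
#' Committed progenitors divide at rate `r_n` through at most `L`
#' generations; generations below `L` die at rate `mu_n`, the terminal
#' generation dies at rate `mu_nL` or matures into circulating
#' granulocytes at rate `omega`; mature granulocytes die at rate `mu_m`.
#' All rates per day.  `L` may be non-integer, in which case it is read as
#' the effective maximum generation of the continuously interpolated
#' burst solutions.
#'
#' @param r_n Progenitor division rate (1/day).
#' @param L Maximum progenitor generation (> 0; non-integer allowed).
#' @param mu_n Progenitor death rate for generations below `L` (1/day).
#' @param mu_nL Death rate of generation-`L` progenitors (1/day).
#' @param omega Maturation rate of generation-`L` progenitors (1/day).
#' @param mu_m Mature granulocyte death rate (1/day).
#' @return An object of class `progenitor_rates`.
#' @export
progenitor_rates <- function(r_n = 2.5, L = 23.4, mu_n = 0, mu_nL = 0,
                             omega = 0.16, mu_m = 1) {
  vals <- c(r_n = r_n, L = L, mu_n = mu_n, mu_nL = mu_nL,
            omega = omega, mu_m = mu_m)
  if (any(!is.finite(vals))) stop("all rates must be finite numbers")
  if (any(vals < 0)) stop("all rates must be non-negative")
  if (L <= 0) stop("L must be positive")
  if (omega <= 0) stop("omega must be positive")
  if (mu_m <= 0) stop("mu_m must be positive")
  structure(as.list(vals), class = "progenitor_rates")
}

#' Mean granulocyte output per differentiation event
#'
#' The average number of mature granulocytes ultimately produced by one
#' HSC differentiation event:
#' `beta = omega / (omega + mu_nL) * (2 r_n / (r_n + mu_n))^L`.
#'
#' @param prog A [progenitor_rates()].
#' @return `beta` (cells per event).
#' @export
beta_amplification <- function(prog) {
  stopifnot(inherits(prog, "progenitor_rates"))
  with(prog, omega / (omega + mu_nL) * (2 * r_n / (r_n + mu_n))^L)
}

#' Effective maximum progenitor generation
#'
#' Progenitor death and the maturation/death competition at the terminal
#' generation reduce the realized amplification below `2^L`; the
#' effective generation count absorbing both is
#' `L_e = L - L log2((r_n + mu_n) / r_n) - log2((omega + mu_nL) / omega)`,
#' so that `beta = 2^L_e` exactly.
#'
#' @param prog A [progenitor_rates()].
#' @return `L_e` (generations; generally non-integer).
#' @export
effective_generation <- function(prog) {
  stopifnot(inherits(prog, "progenitor_rates"))
  if (prog$r_n <= 0) stop("r_n must be positive")
  with(prog,
       L - L * log2((r_n + mu_n) / r_n) - log2((omega + mu_nL) / omega))
}

#' Steady-state granulocyte balance between differentiation flux and pool
#'
#' At steady state, the tagged differentiation flux amplified through the
#' progenitor cascade balances granulocyte turnover:
#' `A_ss_plus * 2^L_e = M_ss_plus * mu_m`.  `ass_plus_from_Le` solves for
#' the total tagged differentiation rate given `L_e`; `Le_from_ass_plus`
#' is its exact inverse.
#'
#' @param M_ss_plus Tagged peripheral granulocyte pool at steady state
#'   (cells).
#' @param mu_m Mature granulocyte death rate (1/day).
#' @param L_e Effective maximum generation.
#' @param A_ss_plus Total tagged HSC differentiation rate (events/day).
#' @return A rate in events/day, or a generation count.
#' @export
ass_plus_from_Le <- function(M_ss_plus, mu_m, L_e) {
  stopifnot(M_ss_plus > 0, mu_m > 0)
  M_ss_plus * mu_m * 2^(-L_e)
}

#' @rdname ass_plus_from_Le
#' @export
Le_from_ass_plus <- function(M_ss_plus, mu_m, A_ss_plus) {
  stopifnot(M_ss_plus > 0, mu_m > 0, A_ss_plus > 0)
  log2(M_ss_plus * mu_m / A_ss_plus)
}

#' Correct a tagged differentiation rate for the tagged fraction
#'
#' The inferred rate refers to tagged (EGFP+) HSCs only; dividing by the
#' tagged fraction estimates the whole-animal differentiation rate.
#'
#' @param A_ss_plus Tagged differentiation rate (events/day).
#' @param egfp_fraction Fraction of cells carrying the tag, in (0, 1\].
#' @return Total differentiation rate (events/day).
#' @export
total_differentiation_rate <- function(A_ss_plus, egfp_fraction) {
  stopifnot(A_ss_plus >= 0, egfp_fraction > 0, egfp_fraction <= 1)
  A_ss_plus / egfp_fraction
}

#' Progenitor generation populations after a single differentiation event
#'
#' One HSC differentiation deposits a single generation-0 progenitor at
#' `t = 0`.  Generations below the terminal one follow
#' `n_b^(l)(t) = (2 r_n t)^l / Gamma(l + 1) * exp(-(r_n + mu_n) t)`,
#' continued to non-integer `l` through the gamma function.
#'
#' @param t Times (days), non-negative.
#' @param l Generation index (>= 0; non-integer allowed).
#' @param prog A [progenitor_rates()].
#' @return Cell counts at `t`.
#' @export
burst_generation <- function(t, l, prog) {
  stopifnot(inherits(prog, "progenitor_rates"), l >= 0, all(t >= 0))
  # at t = 0: 1 cell for l = 0, none in later generations (log underflows)
  exp(l * log(pmax(2 * prog$r_n * t, .Machine$double.xmin)) -
        lgamma(l + 1) - (prog$r_n + prog$mu_n) * t)
}

# Closed-form terminal-generation population n_b^(L)(t): the convolution
# of 2 r_n n_b^(L-1) with exp(-(omega + mu_nL) t) reduces to a lower
# incomplete gamma (pgamma) when r_n + mu_n > omega + mu_nL.
burst_nL_closed <- function(t, prog) {
  a <- prog$r_n + prog$mu_n          # decay of generations < L
  cc <- prog$omega + prog$mu_nL      # decay of generation L
  L <- prog$L
  if (a <= cc) return(NULL)          # closed form unavailable
  (2 * prog$r_n / (a - cc))^L * exp(-cc * t) * stats::pgamma((a - cc) * t, L)
}

#' Terminal-generation population of a single burst
#'
#' Closed-form `n_b^(L)(t)` via the lower incomplete gamma function,
#' valid when `r_n + mu_n > omega + mu_nL` (the physiological ordering).
#'
#' @param t Times (days).
#' @param prog A [progenitor_rates()].
#' @return Cell counts at `t`.
#' @export
burst_terminal <- function(t, prog) {
  stopifnot(inherits(prog, "progenitor_rates"), all(t >= 0))
  out <- burst_nL_closed(t, prog)
  if (is.null(out)) {
    stop("closed form requires r_n + mu_n > omega + mu_nL; ",
         "use burst_kernel(method = 'ode')")
  }
  out
}

# Closed-form mature-cell burst m_b(t) = omega * (n_b^(L) conv exp(-mu_m t)),
# valid when r_n + mu_n > mu_m and mu_m != omega + mu_nL and
# r_n + mu_n > omega + mu_nL.
burst_mb_closed <- function(t, prog) {
  a <- prog$r_n + prog$mu_n
  cc <- prog$omega + prog$mu_nL
  b <- prog$mu_m
  L <- prog$L
  if (a <= cc || a <= b || abs(b - cc) < 1e-12) return(NULL)
  K <- (2 * prog$r_n / (a - cc))^L
  prog$omega * K / (b - cc) *
    (exp(-cc * t) * stats::pgamma((a - cc) * t, L) -
       exp(-b * t) * ((a - cc) / (a - b))^L * stats::pgamma((a - b) * t, L))
}

#' Granulocyte burst kernel for one differentiation event
#'
#' Computes the deterministic mature-granulocyte response `m_b(t)` to a
#' single HSC differentiation at `t = 0`, on a uniform evaluation grid.
#' Closed forms through the lower incomplete gamma function are used when
#' the rate ordering permits (`r_n + mu_n` exceeding both `mu_m` and
#' `omega + mu_nL`, the physiological regime); otherwise the terminal and
#' mature compartments are integrated as ODEs forced by the analytic
#' upstream generations.  The kernel integrates to `beta / mu_m` cells x
#' days and carries total burst mass `beta = 2^L_e`.
#'
#' @param prog A [progenitor_rates()] (here `L` is interpreted as the
#'   effective generation when `mu_n = mu_nL = 0`).
#' @param t_max Grid end (days); must be large enough that the burst has
#'   decayed below one cell.
#' @param dt Grid step (days).
#' @param method `"closed"` (incomplete-gamma closed form, default) or
#'   `"ode"` (deSolve integration; the independent cross-check route).
#' @return An object of class `burst_kernel`: list with `times`, `m_b`,
#'   `n_L`, the rate set, `mass_beta`, and the closed-form evaluator
#'   `mb_fun` when available.
#' @export
burst_kernel <- function(prog, t_max = 200, dt = 0.25,
                         method = c("closed", "ode")) {
  stopifnot(inherits(prog, "progenitor_rates"), t_max > 0, dt > 0)
  method <- match.arg(method)
  times <- seq(0, t_max, by = dt)
  mb_fun <- NULL
  if (method == "closed") {
    mb <- burst_mb_closed(times, prog)
    nL <- burst_nL_closed(times, prog)
    if (is.null(mb) || is.null(nL)) method <- "ode"
    else mb_fun <- function(t) burst_mb_closed(t, prog)
  }
  if (method == "ode") {
    a <- prog$r_n + prog$mu_n
    cc <- prog$omega + prog$mu_nL
    force_in <- function(t) {
      # flux 2 r_n n_b^(L-1)(t) into the terminal generation
      2 * prog$r_n *
        exp((prog$L - 1) * log(pmax(2 * prog$r_n * t,
                                    .Machine$double.xmin)) -
              lgamma(prog$L) - a * t)
    }
    deriv <- function(t, y, parms) {
      list(c(force_in(t) - cc * y[1],
             prog$omega * y[1] - prog$mu_m * y[2]))
    }
    sol <- deSolve::ode(c(nL = 0, m = 0), times, deriv, NULL,
                        method = "lsoda", rtol = 1e-10, atol = 1e-8)
    nL <- sol[, "nL"]
    mb <- sol[, "m"]
  }
  if (mb[length(mb)] >= 1) {
    stop("burst kernel truncated: m_b(t_max) >= 1 cell; increase t_max")
  }
  structure(list(times = times, m_b = mb, n_L = nL, rates = prog,
                 mass_beta = beta_amplification(prog), mb_fun = mb_fun,
                 method = method),
            class = "burst_kernel")
}

#' @export
print.burst_kernel <- function(x, ...) {
  cat("<burst_kernel> L = ", x$rates$L, ", r_n = ", x$rates$r_n,
      ", beta = ", format(x$mass_beta, digits = 4),
      ", peak m_b = ", format(max(x$m_b), digits = 4),
      " at t = ", x$times[which.max(x$m_b)], " d\n", sep = "")
  invisible(x)
}

#' Detectable duration of a single granulocyte burst
#'
#' Total time during which the burst population `m_b(t)` exceeds a
#' detection threshold (by default the inverse sampling fraction
#' `M_ss_plus / S_plus`, the pool size below which a clone is likely
#' missed in a blood sample).  Crossings are refined by root bracketing
#' on the kernel's evaluator, so the result does not depend on the
#' storage grid step.
#'
#' @param kernel A [burst_kernel()].
#' @param threshold_cells Detection threshold (cells).
#' @return Width in days (0 if the peak never reaches the threshold).
#' @export
burst_width <- function(kernel, threshold_cells) {
  stopifnot(inherits(kernel, "burst_kernel"), threshold_cells > 0)
  f <- if (!is.null(kernel$mb_fun)) {
    function(t) kernel$mb_fun(t) - threshold_cells
  } else {
    function(t) stats::approx(kernel$times, kernel$m_b, t,
                              rule = 2)$y - threshold_cells
  }
  v <- kernel$m_b - threshold_cells
  if (max(v) <= 0) return(0)
  s <- sign(v)
  idx <- which(s[-1] * s[-length(s)] < 0)
  crossings <- vapply(idx, function(k) {
    stats::uniroot(f, lower = kernel$times[k], upper = kernel$times[k + 1],
                   tol = 1e-8)$root
  }, numeric(1))
  # assemble above-threshold intervals from the ordered crossings
  above_start <- v[1] > 0
  pts <- c(if (above_start) kernel$times[1], crossings,
           if (v[length(v)] > 0) kernel$times[length(kernel$times)])
  sum(pts[seq(2, length(pts), by = 2)] - pts[seq(1, length(pts), by = 2)])
}

#' Export a burst kernel as two-column TSV
#'
#' @param kernel A [burst_kernel()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_burst_kernel <- function(kernel, path) {
  utils::write.table(data.frame(t_days = kernel$times, m_b = kernel$m_b),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Integrate the lumped deterministic compartment model
#'
#' Couples the logistic HSC pool to the generation ladder of progenitor
#' pools and the mature granulocyte pool:
#' `dH/dt = (p_h (1 - H/K_h) - mu_h) H`,
#' `dN0/dt = alpha H - (r_n + mu_n) N0`,
#' `dNl/dt = 2 r_n N(l-1) - (r_n + mu_n) Nl` for `l < L`,
#' `dNL/dt = 2 r_n N(L-1) - (omega + mu_nL) NL`,
#' `dM/dt = omega NL - mu_m M`.
#' Requires integer `L` (the ladder is only defined generation by
#' generation).
#'
#' @param hsc An [hsc_rates()].
#' @param prog A [progenitor_rates()] with integer `L`.
#' @param alpha Per-cell HSC differentiation rate (1/day).
#' @param t_end End time (days).
#' @param n_out Number of equally spaced output times.
#' @return A data.frame with columns `time`, `H`, `N0` ... `NL`, `M`.
#' @export
integrate_lumped_model <- function(hsc, prog, alpha, t_end, n_out = 201) {
  stopifnot(inherits(hsc, "hsc_rates"), inherits(prog, "progenitor_rates"),
            alpha >= 0, t_end > 0)
  L <- prog$L
  if (L != round(L)) stop("the generation ladder requires integer L")
  L <- as.integer(L)
  times <- seq(0, t_end, length.out = n_out)
  deriv <- function(t, y, p) {
    H <- y[1]; N <- y[2:(L + 2)]; M <- y[L + 3]
    dH <- (hsc$p_h * (1 - H / hsc$K_h) - hsc$mu_h) * H
    dN <- numeric(L + 1)
    dN[1] <- alpha * H - (prog$r_n + prog$mu_n) * N[1]
    if (L >= 2) {
      for (l in 2:L) {
        dN[l] <- 2 * prog$r_n * N[l - 1] - (prog$r_n + prog$mu_n) * N[l]
      }
    }
    dN[L + 1] <- 2 * prog$r_n * N[L] - (prog$omega + prog$mu_nL) * N[L + 1]
    dM <- prog$omega * N[L + 1] - prog$mu_m * M
    list(c(dH, dN, dM))
  }
  y0 <- c(hsc$H0, numeric(L + 1), 0)
  names(y0) <- c("H", paste0("N", 0:L), "M")
  sol <- deSolve::ode(y0, times, deriv, NULL, method = "lsoda",
                      rtol = 1e-9, atol = 1e-6)
  if (attr(sol, "istate")[1] < 0) {
    stop("stiff integration failure; istate = ", attr(sol, "istate")[1])
  }
  as.data.frame(sol)
}
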