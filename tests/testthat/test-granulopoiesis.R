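test_that("effective generation absorbs death and maturation competition", {
  expect_equal(effective_generation(progenitor_rates(L = 12, mu_n = 0,
                                                     mu_nL = 0)), 12)
  prog <- progenitor_rates(r_n = 2.5, L = 18, mu_n = 0.25, mu_nL = 0,
                           omega = 0.16)
  expect_equal(effective_generation(prog), 18 - 18 * log2(1.1),
               tolerance = 1e-12)
  # algebraic identity beta = 2^L_e over random parameter sets
  set.seed(1)
  for (i in 1:100) {
    p <- progenitor_rates(r_n = runif(1, 0.5, 5), L = runif(1, 5, 26),
                          mu_n = runif(1, 0, 0.3),
                          mu_nL = runif(1, 0, 0.27),
                          omega = runif(1, 0.1, 0.3),
                          mu_m = runif(1, 0.2, 2))
    expect_rel_equal(2^effective_generation(p), beta_amplification(p),
                     1e-12)
  }
})

test_that("steady-state balance solves for the flux and round-trips", {
  M <- 1.664e8  # 3.2e9 granulocytes x 0.052 tagged fraction
  expect_equal(ass_plus_from_Le(M, 1, log2(M * 1)), 1)
  expect_equal(ass_plus_from_Le(M, 1, 23.4), 15.0, tolerance = 5e-3)
  expect_equal(Le_from_ass_plus(M, 1, 14.7), 23.43, tolerance = 1e-3)
  for (Le in c(19, 23.4, 28)) {
    expect_rel_equal(Le_from_ass_plus(M, 1, ass_plus_from_Le(M, 1, Le)),
                     Le, 1e-12)
  }
})

test_that("EGFP fraction correction recovers whole-animal rates", {
  expect_equal(total_differentiation_rate(14.7, 0.052), 282.7,
               tolerance = 1e-4)
  expect_error(total_differentiation_rate(10, 0), "egfp_fraction")
})

test_that("single-burst generations start from one generation-0 cell", {
  prog <- progenitor_rates(L = 23.4)
  expect_equal(burst_generation(0, 0, prog), 1)
  expect_equal(burst_generation(0, 5, prog), 0)
  expect_equal(burst_generation(0.8, 3, prog),
               (2 * 2.5 * 0.8)^3 / 6 * exp(-2.5 * 0.8))
})

test_that("burst kernel conserves mass for integer and non-integer L", {
  for (L in c(3, 8, 8.7, 23.4)) {
    prog <- progenitor_rates(L = L, mu_n = 0, mu_nL = 0)
    mass_nL <- stats::integrate(function(t) {
      prog$omega * burst_terminal(t, prog)
    }, 0, Inf, rel.tol = 1e-9)$value
    expect_rel_equal(mass_nL, 2^L, 1e-6)
    k <- burst_kernel(prog, t_max = if (L > 20) 200 else 120)
    mass_mb <- stats::integrate(k$mb_fun, 0, Inf, rel.tol = 1e-9)$value
    expect_rel_equal(mass_mb, 2^L / prog$mu_m, 1e-6)
  }
})

test_that("kernel rises from zero, stays non-negative, and decays", {
  k <- burst_kernel(progenitor_rates(L = 23.4))
  expect_equal(k$m_b[1], 0)
  expect_true(all(k$m_b >= 0))
  expect_lt(k$m_b[length(k$m_b)], 1)
  expect_error(burst_kernel(progenitor_rates(L = 23.4), t_max = 50),
               "truncated")
})

test_that("closed-form and ODE kernel routes agree", {
  prog <- progenitor_rates(L = 23.4)
  kc <- burst_kernel(prog, method = "closed")
  ko <- burst_kernel(prog, method = "ode")
  scale <- max(kc$m_b)
  expect_lt(max(abs(kc$m_b - ko$m_b)) / scale, 1e-6)
  expect_lt(max(abs(kc$n_L - ko$n_L)) / max(kc$n_L), 1e-6)
})

test_that("impulse response of the full generation ladder matches the
           analytic burst solutions at integer L", {
  L <- 6
  prog <- progenitor_rates(r_n = 2.5, L = L, mu_n = 0.1, mu_nL = 0.2,
                           omega = 0.16, mu_m = 1)
  times <- seq(0, 80, by = 0.25)
  deriv <- function(t, y, p) {
    dN <- numeric(L + 2)
    dN[1] <- -(prog$r_n + prog$mu_n) * y[1]
    for (l in 2:L) {
      dN[l] <- 2 * prog$r_n * y[l - 1] - (prog$r_n + prog$mu_n) * y[l]
    }
    dN[L + 1] <- 2 * prog$r_n * y[L] - (prog$omega + prog$mu_nL) * y[L + 1]
    dN[L + 2] <- prog$omega * y[L + 1] - prog$mu_m * y[L + 2]
    list(dN)
  }
  sol <- deSolve::ode(c(1, numeric(L + 1)), times, deriv, NULL,
                      rtol = 1e-10, atol = 1e-12)
  for (l in c(0, 2, L - 1)) {
    analytic <- burst_generation(times, l, prog)
    expect_lt(max(abs(sol[, l + 2] - analytic)) / max(analytic), 1e-5)
  }
  nL <- burst_terminal(times, prog)
  expect_lt(max(abs(sol[, L + 2] - nL)) / max(nL), 1e-5)
  mb <- burst_kernel(prog, t_max = 80)$mb_fun(times)
  expect_lt(max(abs(sol[, L + 3] - mb)) / max(mb), 1e-5)
})

test_that("burst width measures the above-threshold time", {
  k <- burst_kernel(progenitor_rates(L = 23.4))
  expect_equal(burst_width(k, 1e12), 0)  # threshold above the peak
  w <- burst_width(k, 2e4)
  expect_gt(w, 25); expect_lt(w, 40)
  # non-decreasing in L at fixed rates and threshold
  widths <- vapply(18:26, function(L) {
    burst_width(burst_kernel(progenitor_rates(L = L)), 2e4)
  }, numeric(1))
  expect_true(all(diff(widths) >= 0))
  # width in the 1-2 month range under fitted parameters
  expect_gt(w / 30.4, 1); expect_lt(w / 30.4, 2)
})

test_that("lumped compartment model reaches the analytic steady state", {
  hsc <- hsc_rates(p_h = 0.5, K_h = 1000, mu_h = 0.1, H0 = 10)
  prog <- progenitor_rates(r_n = 2.5, L = 5, mu_n = 0.1, mu_nL = 0.2,
                           omega = 0.16, mu_m = 1)
  out0 <- integrate_lumped_model(hsc, prog, alpha = 0, t_end = 200)
  expect_lt(max(abs(utils::tail(out0, 1)[, -(1:2)])), 1e-8)
  alpha <- 0.01
  out <- integrate_lumped_model(hsc, prog, alpha, t_end = 400)
  H_inf <- hsc$K_h * (1 - hsc$mu_h / hsc$p_h)
  expect_rel_equal(utils::tail(out$H, 1), H_inf, 1e-6)
  M_ss <- alpha * H_inf * beta_amplification(prog) / prog$mu_m
  expect_rel_equal(utils::tail(out$M, 1), M_ss, 1e-6)
  expect_error(integrate_lumped_model(hsc, progenitor_rates(L = 5.5),
                                      0.01, 100), "integer L")
})
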