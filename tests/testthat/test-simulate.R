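test_that("effective params pin the flux to the steady-state balance", {
  p <- effective_params(L_e = 23.4, M_ss_plus = 1.664e8)
  expect_equal(p$A_ss_plus, 1.664e8 * 2^(-23.4))
  p2 <- effective_params(L_e = 20, A_ss_plus = 3)
  expect_equal(p2$A_ss_plus, 3)
  expect_error(effective_params(L_e = 20), "M_ss_plus or A_ss_plus")
})

test_that("clones without differentiation events stay at zero", {
  design <- desk_design(J = 4)
  params <- effective_params(lam = 0, C_h = 3, L_e = 23.4,
                             A_ss_plus = 1e-9)
  cfg <- draw_hsc_config(hsc_clone_law(0, 3), seed = 1)
  trajs <- simulate_clones(cfg, params, design, seed = 2)
  expect_true(all(trajs$m[trajs$n_events == 0, ] == 0))
  expect_true(all(trajs$m == 0))  # rate ~ 3e-10/day over ~1300 days
})

test_that("simulation is reproducible and clone sub-streams are stable", {
  design <- desk_design(J = 4)
  params <- effective_params(lam = 0.9, C_h = 20,
                             M_ss_plus = design$M_ss_plus)
  cfg <- draw_hsc_config(hsc_clone_law(0.9, 20), seed = 3)
  k <- burst_kernel(params$prog)
  t1 <- simulate_clones(cfg, params, design, seed = 7, kernel = k)
  t2 <- simulate_clones(cfg, params, design, seed = 7, kernel = k)
  expect_identical(t1$m, t2$m)
  # adding clones must not perturb the original clones' event draws
  cfg30 <- cloneburst:::new_hsc_config(c(cfg$h, rep(1, 10)))
  params30 <- effective_params(lam = 0.9, C_h = 30,
                               A_ss_plus = params$A_ss_plus *
                                 cfg30$H_plus / cfg$H_plus)
  t3 <- simulate_clones(cfg30, params30, design, seed = 7, kernel = k)
  expect_equal(t3$n_events[1:20], t1$n_events)
})

test_that("time-averaged clone pools obey the shot-noise mean", {
  # Campbell's theorem: E[m_i] = alpha h_i * beta / mu_m
  design <- desk_design(J = 8)
  C <- 10
  params <- effective_params(lam = 0, C_h = C, L_e = 23.4,
                             M_ss_plus = design$M_ss_plus)
  cfg <- draw_hsc_config(hsc_clone_law(0, C), seed = 1)
  k <- burst_kernel(params$prog)
  expected <- params$A_ss_plus / C * beta_amplification(params$prog)
  vals <- unlist(lapply(1:60, function(r) {
    simulate_clones(cfg, params, design, seed = 1000 + r, kernel = k)$m
  }))
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - expected), 3 * se)
})

test_that("sparse clones occupy samples at rate alpha*h*burst_width", {
  design <- experiment_design(seq(7, by = 5, length.out = 40), 1.5e4,
                              1.664e8)
  C <- 5
  rate <- 0.002  # events per day per clone; alpha*h*width ~ 0.065 << 1
  params <- effective_params(lam = 0, C_h = C, L_e = 23.4,
                             A_ss_plus = rate * C)
  cfg <- draw_hsc_config(hsc_clone_law(0, C), seed = 2)
  k <- burst_kernel(params$prog)
  thr <- 2e4
  width <- burst_width(k, thr)
  hits <- unlist(lapply(1:50, function(r) {
    simulate_clones(cfg, params, design, seed = 5000 + r, kernel = k)$m > thr
  }))
  p_expect <- rate * width
  se <- sqrt(p_expect * (1 - p_expect) / length(hits))
  expect_lt(abs(mean(hits) - p_expect), 3 * se)
})

test_that("aggregate pool recovers the steady-state tagged pool", {
  design <- desk_design(J = 8)
  params <- effective_params(lam = 0.99, C_h = 50,
                             M_ss_plus = design$M_ss_plus)
  k <- burst_kernel(params$prog)
  pools <- unlist(lapply(1:100, function(r) {
    cfg <- draw_hsc_config(hsc_clone_law(0.99, 50), seed = 300 + r)
    aggregate_pool(simulate_clones(cfg, params, design,
                                   seed = 700 + r, kernel = k))
  }))
  se <- stats::sd(pools) / sqrt(length(pools))
  expect_lt(abs(mean(pools) - design$M_ss_plus), 3 * se)
  # single clone: aggregate equals that clone's row; empty-rate clones: 0
  cfg1 <- cloneburst:::new_hsc_config(5)
  t1 <- simulate_clones(cfg1, params, design, seed = 4, kernel = k)
  expect_equal(aggregate_pool(t1), t1$m[1, ])
})

test_that("clones with equal h are exchangeable in distribution", {
  design <- desk_design(J = 6)
  C <- 4
  params <- effective_params(lam = 0, C_h = C, L_e = 22,
                             M_ss_plus = design$M_ss_plus)
  cfg <- draw_hsc_config(hsc_clone_law(0, C), seed = 1)
  k <- burst_kernel(params$prog)
  m <- lapply(1:80, function(r) {
    simulate_clones(cfg, params, design, seed = 40 + r, kernel = k)$m
  })
  per_clone <- sapply(seq_len(C), function(i) {
    unlist(lapply(m, function(x) x[i, ]))
  })
  means <- colMeans(per_clone)
  ses <- apply(per_clone, 2, stats::sd) / sqrt(nrow(per_clone))
  for (i in 2:C) {
    expect_lt(abs(means[i] - means[1]),
              4 * sqrt(ses[i]^2 + ses[1]^2))
  }
})

test_that("burstier kernels produce larger temporal variance at fixed mean", {
  design <- desk_design(J = 8)
  # equal mean pool (rate * beta constant), different burst mass
  run_var <- function(L_e, rate) {
    params <- effective_params(lam = 0, C_h = 1, L_e = L_e,
                               A_ss_plus = rate)
    cfg <- cloneburst:::new_hsc_config(1)
    k <- burst_kernel(params$prog)
    vals <- unlist(lapply(1:40, function(r) {
      simulate_clones(cfg, params, design, seed = 9000 + r, kernel = k)$m
    }))
    stats::var(vals)
  }
  base_rate <- 0.05
  v_small <- run_var(20, base_rate * 2^(23.4 - 20))
  v_big <- run_var(23.4, base_rate)
  expect_gt(v_big, v_small)
})
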