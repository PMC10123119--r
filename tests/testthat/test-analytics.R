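test_that("demand coefficients match the closed forms and their limits", {
  # no miRNA: rho_T reduces to n alpha / (kappa beta), complex demand 0
  p <- translation_params(eta_plus = 0, n_T = 1, alpha_T = 50, kappa_T = 100,
                          beta_T = 0.5)
  rho <- demand_coefficients(p)
  expect_equal(rho$rho_T, 1)
  expect_equal(rho$rho_TQ, 0)
  # direct arithmetic on the monitor demand
  p2 <- translation_params(n_C = 2, alpha_C = 1, kappa_C = 4, beta_C = 0.5)
  expect_equal(demand_coefficients(p2)$rho_C, 1)
  # the eta -> 0 limit is continuous (no division blow-up)
  rho_eps <- demand_coefficients(set_params(p, eta_plus = 1e-12))
  expect_equal(rho_eps$rho_T, 1, tolerance = 1e-9)
  expect_equal(rho_eps$rho_TQ, 0, tolerance = 1e-9)
})

test_that("miRNA regulation lowers the total miTarget resource demand", {
  set.seed(11)
  for (i in 1:50) {
    p <- rand_translation_params()
    with_mir <- demand_coefficients(p)
    no_mir <- demand_coefficients(set_params(p, eta_plus = 0))
    expect_lt(with_mir$rho_T + with_mir$rho_TQ, no_mir$rho_T)
  }
})

test_that("steady-state summary follows the resource-allocation forms", {
  # symmetric genes without regulation express identically
  p <- translation_params(eta_plus = 0, alpha_C = 80, beta_C = 0.2,
                          gamma_C = 2, delta_C = 0.08, kappa_C = 100,
                          alpha_T = 80, beta_T = 0.2, gamma_T = 2,
                          delta_T = 0.08, kappa_T = 100, n_T = 1, n_C = 1)
  ss <- steady_state(p)
  expect_equal(ss$p_T_bar, ss$p_C_bar)
  # unit-demand arithmetic: rho_T = rho_C = 1, gamma/delta = 1, r_total = 3
  p1 <- translation_params(eta_plus = 0, n_T = 1, n_C = 1,
                           alpha_T = 50, alpha_C = 50,
                           kappa_T = 100, kappa_C = 100,
                           beta_T = 0.5, beta_C = 0.5,
                           gamma_C = 1, delta_C = 1, r_total = 3)
  expect_equal(steady_state(p1)$p_C_bar, 1)
  # random draws agree with the independently coded closed forms
  set.seed(5)
  for (i in 1:20) {
    pr <- rand_translation_params()
    got <- steady_state(pr)
    ref <- oracle_steady_state(pr)
    expect_equal(got$p_T_bar, ref$p_T, tolerance = 1e-12)
    expect_equal(got$p_C_bar, ref$p_C, tolerance = 1e-12)
    expect_equal(got$r_bar, ref$r, tolerance = 1e-12)
    expect_lte(got$r_bar, pr$r_total)
  }
})

test_that("steady state responds monotonically to the binding constant", {
  grid <- default_eta_grid()
  for (sg in c(0, 1)) {
    p <- translation_params(sigma = sg)
    ss <- lapply(grid, function(e) steady_state(set_params(p, eta_plus = e)))
    p_C <- vapply(ss, `[[`, numeric(1), "p_C_bar")
    p_T <- vapply(ss, `[[`, numeric(1), "p_T_bar")
    r <- vapply(ss, `[[`, numeric(1), "r_bar")
    d_C <- vapply(ss, `[[`, numeric(1), "density_C")
    expect_true(all(diff(p_C) > 0))
    expect_true(all(diff(p_T) < 0))
    expect_true(all(diff(r) > 0))
    expect_true(all(diff(d_C) > 0))
    if (sg == 0) {
      d_T <- vapply(ss, `[[`, numeric(1), "density_T")
      expect_true(all(diff(d_T) > 0))
    }
  }
})

test_that("5'UTR sites downregulate the target harder than 3'UTR sites", {
  for (eta in c(0.05, 0.5, 5)) {
    s5 <- steady_state(translation_params(eta_plus = eta, sigma = 0))
    s3 <- steady_state(translation_params(eta_plus = eta, sigma = 1))
    expect_lt(s5$p_T_bar, s3$p_T_bar)
    expect_gt(s5$p_C_bar, s3$p_C_bar)
  }
})

test_that("target-site count ordering holds on any positive eta base", {
  set.seed(3)
  for (i in 1:10) {
    base <- 10^stats::runif(1, -2, 0.5)
    for (sg in c(0, 1)) {
      p <- translation_params(sigma = sg)
      lv <- vapply(c(0, 1, 3) * base, function(e)
        steady_state(set_params(p, eta_plus = e))$p_C_bar, numeric(1))
      expect_true(all(diff(lv) > 0))  # Control < 1TS < 3TS
    }
  }
})

test_that("allocation fractions account for the whole ribosome pool", {
  set.seed(9)
  for (i in 1:20) {
    p <- rand_translation_params()
    ss <- steady_state(p)
    total <- (1 + ss$rho$rho_T + p$sigma * ss$rho$rho_TQ + ss$rho$rho_C) *
      ss$r_bar / p$r_total
    expect_equal(total, 1, tolerance = 1e-12)
  }
})
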