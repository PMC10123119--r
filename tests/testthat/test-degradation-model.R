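# single-substrate enzymatic decay integrated directly in the test: the
# independent oracle for the endogenous gene when no miRNA couples it to
# the miTarget block
single_substrate_ode <- function(p, m0, s0, times, production = FALSE) {
  rhs <- function(t, x, parms) {
    z <- p$z_total - x[["s"]]
    list(c(m = (if (production) p$n_E * p$alpha_E else 0) -
             p$betaE_assoc * z * x[["m"]] + p$betaE_dissoc * x[["s"]],
           s = p$betaE_assoc * z * x[["m"]] -
             (p$betaE_dissoc + p$betaE_cat) * x[["s"]]))
  }
  deSolve::ode(y = c(m = m0, s = s0), times = times, func = rhs,
               parms = NULL, method = "radau", atol = 1e-11, rtol = 1e-8)
}

test_that("free RNase is conserved and never driven negative", {
  p <- degradation_params(eta_plus = 4)
  sol <- deSolve::ode(y = degradation_state(), times = seq(0, 200, by = 10),
                      func = degradation_rhs, parms = p, method = "radau",
                      atol = 1e-9, rtol = 1e-6)
  complexes <- sol[, "s_T"] + sol[, "s_Q"] + sol[, "s_E"]
  expect_true(all(complexes <= p$z_total * (1 + 1e-9)))
  expect_gte(min(sol[, -1]), -1e-8)
  # a state claiming more bound RNase than the pool holds is rejected
  bad <- degradation_state(s_T = 200, s_E = 100)
  expect_error(degradation_rhs(0, bad, p), "conservation")
})

test_that("without miRNA the endogenous gene is independent of the target", {
  p <- set_params(degradation_params(), eta_plus = 0,
                  betaT_assoc = 1e-6, alpha_T = 1e-4)
  # miTarget block effectively removed: compare against the stand-alone
  # single-substrate system from the same initial condition
  times <- seq(0, 12, by = 0.5)
  ss <- suppressWarnings(integrate_to_steady_state("degradation", p))
  full <- deSolve::ode(y = ss, times = times, func = degradation_rhs,
                       parms = p, method = "radau", atol = 1e-9, rtol = 1e-6,
                       transcription_on = FALSE)
  solo <- single_substrate_ode(p, ss[["m_E"]], ss[["s_E"]], times)
  expect_equal(unname(full[, "m_E"]), unname(solo[, "m"]), tolerance = 1e-6)
  expect_equal(unname(full[, "s_E"]), unname(solo[, "s"]), tolerance = 1e-6)
})

test_that("excess enzyme gives first-order decay at the analytic rate", {
  # binding-limited regime: rate = assoc * z_total * cat / (dissoc + cat)
  p <- degradation_params(alpha_E = 0.1, betaE_assoc = 2e-5, z_total = 1000,
                          alpha_T = 1e-3, betaT_assoc = 1e-6, eta_plus = 0)
  times <- seq(0, 12, by = 0.25)
  prof <- suppressWarnings(
    transcription_halt_decay(p, eta_plus_values = 0, sample_times = times,
                             species = "endogenous"))[[1]]
  rate_pred <- p$betaE_assoc * p$z_total * p$betaE_cat /
    (p$betaE_dissoc + p$betaE_cat)
  fit <- stats::lm(log(prof$values) ~ prof$times)
  expect_equal(unname(-coef(fit)[2]), rate_pred, tolerance = 0.02)
  # and the effective first-order rate is constant along the trajectory
  tr <- suppressWarnings(decay_rate_trace(p, eta_plus = 0, times))
  eff <- tr$beta_E_eff[tr$time_h > 1]
  expect_lt(diff(range(eff)) / mean(eff), 0.02)
})

test_that("effective degradation rate is flux over total transcript pool", {
  p <- degradation_params(eta_plus = 2)
  st <- degradation_state(m_T = 10, m_Q = 5, m_E = 8, q = 1,
                          s_T = 3, s_Q = 6, s_E = 4)
  expect_equal(effective_degradation_rate(st, p, "endogenous"),
               p$betaE_cat * 4 / (8 + 4))
  expect_equal(effective_degradation_rate(st, p, "miTarget"),
               (p$betaT_cat * 3 + p$betaTQ_cat * 6) / (10 + 5 + 3 + 6))
  empty <- degradation_state(m_E = 0, s_E = 0, m_T = 1)
  expect_error(effective_degradation_rate(empty, p, "endogenous"), "zero")
})

test_that("miRNA activity sequesters RNases and depresses endogenous decay", {
  p <- degradation_params()
  tr0 <- suppressWarnings(decay_rate_trace(p, eta_plus = 0))
  tr8 <- suppressWarnings(decay_rate_trace(p, eta_plus = 8))
  early <- tr8$time_h <= 2  # phase 1 of the queueing regime
  # the degradation machinery is held in target-derived complexes ...
  expect_true(all(tr8$rnase_bound_target_frac[early] >
                    tr0$rnase_bound_target_frac[early]))
  # ... so the endogenous effective rate drops below the control ...
  expect_true(all(tr8$beta_E_eff[early] < tr0$beta_E_eff[early]))
  # ... and recovers toward the control once the target pool is exhausted
  late8 <- tr8$beta_E_eff[which.max(tr8$time_h)]
  late0 <- tr0$beta_E_eff[which.max(tr0$time_h)]
  expect_gt(late8, 2 * min(tr8$beta_E_eff))
  expect_gt(late8, 0.85 * late0)
})
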