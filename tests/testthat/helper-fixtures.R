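# shared fixtures: random parameter draws and small numeric utilities

rel_err <- function(x, ref) abs(x - ref) / pmax(abs(ref), .Machine$double.eps)

# protocol-respecting random draw (see random_translation_params): spans 4
# decades but rejects sets whose slowest relaxation outlives the 10000-h
# steady-state horizon
rand_translation_params <- function(sigma = NULL) {
  p <- random_translation_params()
  if (!is.null(sigma)) p <- set_params(p, sigma = sigma)
  p
}

# independent evaluation of the closed-form steady state, written out
# directly from the printed formulas (test-side oracle, no package calls
# beyond parameter access)
oracle_steady_state <- function(p) {
  b_TQ <- p$lambda_TQ * p$beta_T
  if (p$eta_plus == 0) {
    rho_T <- p$n_T * p$alpha_T / (p$kappa_T * p$beta_T)
    rho_TQ <- 0
  } else {
    rho_T <- p$n_T * p$alpha_T /
      (p$kappa_T * (p$beta_T + p$alpha_Q * p$eta_plus * b_TQ /
                      (p$beta_Q * (b_TQ + p$eta_minus))))
    rho_TQ <- p$n_T * p$alpha_T /
      (p$kappa_T * (b_TQ + p$beta_T * p$beta_Q * (b_TQ + p$eta_minus) /
                      (p$alpha_Q * p$eta_plus)))
  }
  rho_C <- p$n_C * p$alpha_C / (p$kappa_C * p$beta_C)
  denom <- 1 + rho_C + rho_T + p$sigma * rho_TQ
  list(
    rho_T = rho_T, rho_TQ = rho_TQ, rho_C = rho_C,
    p_T = p$gamma_T / p$delta_T * (rho_T + p$sigma * rho_TQ) / denom *
      p$r_total,
    p_C = p$gamma_C / p$delta_C * rho_C / denom * p$r_total,
    r = p$r_total / denom,
    m_T = rho_T * p$kappa_T, m_Q = rho_TQ * p$kappa_T,
    m_C = p$n_C * p$alpha_C / p$beta_C, q = p$alpha_Q / p$beta_Q
  )
}
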