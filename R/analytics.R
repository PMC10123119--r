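#' Resource demand coefficients
#'
#' Closed-form dimensionless loads that each transcript pool places on the
#' shared ribosome pool at steady state. \code{rho_T} is the demand of free
#' (unbound) miTarget mRNA, \code{rho_TQ} that of the miTarget:miRNA
#' complex, and \code{rho_C} that of the capacity monitor. miRNA regulation
#' lowers \code{rho_T} while raising \code{rho_TQ}, and the total target
#' demand \code{rho_T + rho_TQ} falls strictly as the binding constant
#' \code{eta_plus} grows — the source of the resource-redistribution effect.
#'
#' At \code{eta_plus = 0} the complex demand is taken as its limit,
#' \code{rho_TQ = 0}.
#'
#' @param params a [translation_params()] object.
#' @return An object of class \code{"demand_coefficients"}: a named list
#'   with elements \code{rho_T}, \code{rho_TQ}, \code{rho_C}.
#' @examples
#' demand_coefficients(translation_params(eta_plus = 0))
#' @export
demand_coefficients <- function(params) {
  validate_translation_params(params)
  b_TQ <- beta_TQ(params)
  A_T <- params$n_T * params$alpha_T / params$kappa_T
  if (params$eta_plus == 0) {
    rho_T <- A_T / params$beta_T
    rho_TQ <- 0
  } else {
    x <- params$alpha_Q * params$eta_plus /
      (params$beta_Q * (b_TQ + params$eta_minus))
    rho_T <- A_T / (params$beta_T + x * b_TQ)
    rho_TQ <- A_T / (b_TQ + params$beta_T / x)
  }
  rho_C <- params$n_C * params$alpha_C / (params$kappa_C * params$beta_C)
  structure(list(rho_T = rho_T, rho_TQ = rho_TQ, rho_C = rho_C),
            class = "demand_coefficients")
}

#' @export
print.demand_coefficients <- function(x, ...) {
  cat(sprintf("Resource demand coefficients: rho_T = %.4g, rho_TQ = %.4g, rho_C = %.4g\n",
              x$rho_T, x$rho_TQ, x$rho_C))
  invisible(x)
}

#' Closed-form steady state of the ribosome-competition model
#'
#' Analytic steady-state summary of the translation model. Protein levels
#' follow the resource-allocation form
#' \deqn{\bar p_T = \frac{\gamma_T}{\delta_T}\,
#'   \frac{\rho_T + \sigma\rho_T^Q}{1 + \rho_C + \rho_T + \sigma\rho_T^Q}\,
#'   r^{Total}, \qquad
#'   \bar p_C = \frac{\gamma_C}{\delta_C}\,
#'   \frac{\rho_C}{1 + \rho_T + \sigma\rho_T^Q + \rho_C}\, r^{Total},}
#' with free ribosomes \eqn{\bar r = r^{Total}/(1 + \rho_T + \sigma\rho_T^Q
#' + \rho_C)}. RNA species have the linear closed forms
#' \eqn{\bar m_C = n_C\alpha_C/\beta_C}, \eqn{\bar q = \alpha_Q/\beta_Q}
#' (the miRNA is recycled), \eqn{\bar m_T = \rho_T\kappa_T},
#' \eqn{\bar m_Q = \rho_T^Q\kappa_T}. Ribosomal densities (translating
#' ribosomes per transcript) are \eqn{\bar r/\kappa_C} for the monitor and,
#' averaging over free and complexed target transcripts,
#' \eqn{\bar r(\bar m_T + \sigma\bar m_Q)/(\kappa_T(\bar m_T + \bar m_Q))}
#' for the target.
#'
#' @param params a [translation_params()] object.
#' @return An object of class \code{"steady_state_summary"}: a named list
#'   with \code{p_T_bar}, \code{p_C_bar}, \code{r_bar}, \code{density_T},
#'   \code{density_C}, \code{m_T_bar}, \code{m_Q_bar}, \code{m_C_bar},
#'   \code{q_bar} and the demand coefficients under \code{rho}.
#' @seealso [demand_coefficients()], [integrate_to_steady_state()]
#' @export
steady_state <- function(params) {
  rho <- demand_coefficients(params)
  denom <- 1 + rho$rho_T + params$sigma * rho$rho_TQ + rho$rho_C
  r_bar <- params$r_total / denom
  m_T_bar <- rho$rho_T * params$kappa_T
  m_Q_bar <- rho$rho_TQ * params$kappa_T
  total_T <- m_T_bar + m_Q_bar
  density_T <- if (total_T > 0) {
    r_bar * (m_T_bar + params$sigma * m_Q_bar) / (params$kappa_T * total_T)
  } else {
    r_bar / params$kappa_T  # empty-pool limit: density of a lone transcript
  }
  structure(list(
    p_T_bar = params$gamma_T / params$delta_T *
      (rho$rho_T + params$sigma * rho$rho_TQ) / denom * params$r_total,
    p_C_bar = params$gamma_C / params$delta_C * rho$rho_C / denom *
      params$r_total,
    r_bar = r_bar,
    density_T = density_T,
    density_C = r_bar / params$kappa_C,
    m_T_bar = m_T_bar,
    m_Q_bar = m_Q_bar,
    m_C_bar = params$n_C * params$alpha_C / params$beta_C,
    q_bar = params$alpha_Q / params$beta_Q,
    rho = rho
  ), class = "steady_state_summary")
}

#' @export
print.steady_state_summary <- function(x, ...) {
  cat("Analytic steady state (nM)\n")
  cat(sprintf("  proteins:  p_T = %.4g, p_C = %.4g\n", x$p_T_bar, x$p_C_bar))
  cat(sprintf("  free ribosomes: r = %.4g\n", x$r_bar))
  cat(sprintf("  densities: miTarget = %.4g, monitor = %.4g ribosomes/transcript\n",
              x$density_T, x$density_C))
  cat(sprintf("  RNA: m_T = %.4g, m_Q = %.4g, m_C = %.4g, q = %.4g\n",
              x$m_T_bar, x$m_Q_bar, x$m_C_bar, x$q_bar))
  invisible(x)
}

#' @export
as.data.frame.steady_state_summary <- function(x, ...) {
  data.frame(p_T_bar = x$p_T_bar, p_C_bar = x$p_C_bar, r_bar = x$r_bar,
             density_T = x$density_T, density_C = x$density_C,
             m_T_bar = x$m_T_bar, m_Q_bar = x$m_Q_bar, m_C_bar = x$m_C_bar,
             q_bar = x$q_bar, rho_T = x$rho$rho_T, rho_TQ = x$rho$rho_TQ,
             rho_C = x$rho$rho_C)
}

# the translation-state vector implied by the analytic steady state
steady_state_vector <- function(params) {
  ss <- steady_state(params)
  translation_state(m_T = ss$m_T_bar, m_Q = ss$m_Q_bar, m_C = ss$m_C_bar,
                    q = ss$q_bar, p_T = ss$p_T_bar, p_C = ss$p_C_bar)
}
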