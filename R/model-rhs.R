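#' Free ribosome concentration under competitive loading
#'
#' Quasi-steady-state partition of the fixed ribosome pool over the
#' competing transcript pools. Each transcript class loads ribosomes in
#' proportion to its abundance scaled by its effective dissociation
#' constant; the target-site location switch \code{sigma} gates whether the
#' miRNA-bound target complex sequesters ribosomes at all (with 5'UTR sites,
#' \code{sigma = 0}, steric hindrance keeps the complex ribosome-free).
#'
#' @param state a [translation_state()] vector.
#' @param params a [translation_params()] object.
#' @return Free ribosome concentration (nM):
#'   \code{r_total / (1 + m_T/kappa_T + sigma*m_Q/kappa_T + m_C/kappa_C)}.
#' @examples
#' p <- translation_params()
#' free_ribosomes(translation_state(), p)  # empty cell: the whole pool
#' @export
free_ribosomes <- function(state, params) {
  if (!is.numeric(state) || any(!is.finite(state)))
    stop("state components must be finite numbers", call. = FALSE)
  load <- state[["m_T"]] / params$kappa_T +
    params$sigma * state[["m_Q"]] / params$kappa_T +
    state[["m_C"]] / params$kappa_C
  params$r_total / (1 + load)
}

#' Right-hand side of the ribosome-competition model
#'
#' Mass-action derivatives of the two-gene translation model. The miRNA
#' binds free target mRNA reversibly; the bound complex is degraded at the
#' enhanced rate \code{beta_TQ = lambda_TQ*beta_T}, which releases the miRNA
#' (catalytic RISC). Translation fluxes use the free-ribosome pool from
#' [free_ribosomes()]; with 3'UTR sites (\code{sigma = 1}) the bound complex
#' is translated at the target's rate, with 5'UTR sites it is silent.
#'
#' The signature follows the \pkg{deSolve} convention so the function can be
#' passed directly to [deSolve::ode()].
#'
#' @param t time (h); unused (autonomous system).
#' @param state a [translation_state()] vector.
#' @param params a [translation_params()] object.
#' @return A list holding the named derivative vector.
#' @export
translation_rhs <- function(t, state, params) {
  validate_translation_params(params)
  m_T <- state[["m_T"]]; m_Q <- state[["m_Q"]]; m_C <- state[["m_C"]]
  q <- state[["q"]]; p_T <- state[["p_T"]]; p_C <- state[["p_C"]]
  b_TQ <- beta_TQ(params)
  r <- free_ribosomes(state, params)
  bind <- params$eta_plus * q * m_T
  unbind <- params$eta_minus * m_Q
  d <- c(
    m_T = params$n_T * params$alpha_T - params$beta_T * m_T - bind + unbind,
    m_Q = bind - (params$eta_minus + b_TQ) * m_Q,
    m_C = params$n_C * params$alpha_C - params$beta_C * m_C,
    q   = params$alpha_Q - params$beta_Q * q - bind + unbind + b_TQ * m_Q,
    p_T = params$gamma_T * r * (m_T + params$sigma * m_Q) / params$kappa_T -
      params$delta_T * p_T,
    p_C = params$gamma_C * r * m_C / params$kappa_C - params$delta_C * p_C
  )
  list(d)
}

#' Right-hand side of the finite-RNase degradation model
#'
#' Mass-action derivatives of the degradation-resource model. Free and
#' miRNA-bound target mRNA and the endogenous mRNA compete for a finite
#' RNase pool; association forms degrading complexes (\code{s_T}, \code{s_Q},
#' \code{s_E} — complexes formed from miRNA-bound mRNA are tracked
#' separately so the miRNA released on catalytic completion is bookkept
#' exactly). Free RNase is the conserved remainder
#' \code{z = z_total - s_T - s_Q - s_E}.
#'
#' @param t time (h); unused.
#' @param state a [degradation_state()] vector.
#' @param params a [degradation_params()] object.
#' @param transcription_on logical; when \code{FALSE} all production rate
#'   constants (\code{alpha_T}, \code{alpha_E}, \code{alpha_Q}) are zeroed,
#'   emulating a transcription-halt (DRB-type) experiment.
#' @return A list holding the named derivative vector.
#' @export
degradation_rhs <- function(t, state, params, transcription_on = TRUE) {
  m_T <- state[["m_T"]]; m_Q <- state[["m_Q"]]; m_E <- state[["m_E"]]
  q <- state[["q"]]
  s_T <- state[["s_T"]]; s_Q <- state[["s_Q"]]; s_E <- state[["s_E"]]
  z <- params$z_total - s_T - s_Q - s_E
  if (z < -1e-8 * params$z_total)
    stop("state violates RNase conservation: s_T + s_Q + s_E > z_total",
         call. = FALSE)
  on <- as.numeric(isTRUE(transcription_on))
  bind <- params$eta_plus * q * m_T
  unbind <- params$eta_minus * m_Q
  d <- c(
    m_T = on * params$n_T * params$alpha_T - bind + unbind -
      params$betaT_assoc * z * m_T + params$betaT_dissoc * s_T,
    m_Q = bind - unbind -
      params$betaTQ_assoc * z * m_Q + params$betaT_dissoc * s_Q,
    m_E = on * params$n_E * params$alpha_E -
      params$betaE_assoc * z * m_E + params$betaE_dissoc * s_E,
    q   = on * params$alpha_Q - params$beta_Q * q - bind + unbind +
      params$betaTQ_cat * s_Q,
    s_T = params$betaT_assoc * z * m_T -
      (params$betaT_dissoc + params$betaT_cat) * s_T,
    s_Q = params$betaTQ_assoc * z * m_Q -
      (params$betaT_dissoc + params$betaTQ_cat) * s_Q,
    s_E = params$betaE_assoc * z * m_E -
      (params$betaE_dissoc + params$betaE_cat) * s_E
  )
  list(d)
}

#' Instantaneous effective degradation rate
#'
#' First-order equivalent of the enzymatic degradation of one transcript
#' class: the catalytic flux through its RNase complexes divided by its
#' total (free plus complexed) mRNA. The rate is time-dependent along a
#' trajectory because it tracks RNase availability, which is the model's
#' currency for the queueing effect.
#'
#' @param state a [degradation_state()] vector.
#' @param params a [degradation_params()] object.
#' @param species \code{"miTarget"} (free + miRNA-bound target pools) or
#'   \code{"endogenous"}.
#' @return The effective first-order rate (1/h).
#' @export
effective_degradation_rate <- function(state, params,
                                       species = c("miTarget", "endogenous")) {
  species <- match.arg(species)
  if (species == "miTarget") {
    total <- state[["m_T"]] + state[["m_Q"]] + state[["s_T"]] + state[["s_Q"]]
    flux <- params$betaT_cat * state[["s_T"]] +
      params$betaTQ_cat * state[["s_Q"]]
  } else {
    total <- state[["m_E"]] + state[["s_E"]]
    flux <- params$betaE_cat * state[["s_E"]]
  }
  if (total <= 0)
    stop("effective rate undefined: total ", species, " mRNA is zero",
         call. = FALSE)
  flux / total
}
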