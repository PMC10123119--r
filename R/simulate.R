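#' Integrate a model to steady state
#'
#' Integrates the chosen model from a starting state over a long horizon
#' with the Radau stiff implicit solver (absolute tolerance 1e-9, relative
#' tolerance 1e-6, span 0--10000 h by default) and returns the terminal
#' state. Steady state is the terminal value; the residual of the
#' right-hand side at that point is checked explicitly against the largest
#' production flux and a warning is raised if it has not settled.
#'
#' @param model \code{"translation"} or \code{"degradation"}.
#' @param params the matching parameter object.
#' @param state optional starting state; defaults to the zero state.
#' @param t_end integration horizon (h).
#' @param atol,rtol solver tolerances.
#' @param transcription_on passed to [degradation_rhs()].
#' @return The terminal named state vector, with attributes
#'   \code{"residual"} (max |dx/dt| at the terminal state) and
#'   \code{"converged"}.
#' @examples
#' p <- translation_params(eta_plus = 0)
#' s <- integrate_to_steady_state("translation", p)
#' s[["m_C"]]  # ~ n_C*alpha_C/beta_C
#' @export
integrate_to_steady_state <- function(model = c("translation", "degradation"),
                                      params, state = NULL, t_end = 10000,
                                      atol = 1e-9, rtol = 1e-6,
                                      transcription_on = TRUE) {
  model <- match.arg(model)
  if (model == "translation") {
    validate_translation_params(params)
    if (is.null(state)) state <- translation_state()
    rhs <- translation_rhs
    prod_max <- max(params$n_T * params$alpha_T, params$n_C * params$alpha_C,
                    params$alpha_Q)
    args <- list()
  } else {
    validate_degradation_params(params)
    if (is.null(state)) state <- degradation_state()
    rhs <- degradation_rhs
    prod_max <- max(params$n_T * params$alpha_T, params$n_E * params$alpha_E,
                    params$alpha_Q)
    args <- list(transcription_on = transcription_on)
  }
  check_state(state)
  sol <- do.call(deSolve::ode, c(list(
    y = state, times = c(0, t_end), func = rhs, parms = params,
    method = "radau", atol = atol, rtol = rtol), args))
  if (attr(sol, "istate")[1] < 0)
    stop("stiff integration failed for the ", model, " model", call. = FALSE)
  final <- sol[nrow(sol), -1]
  final <- pmax(final, 0)  # clip solver-scale negative round-off
  deriv <- do.call(rhs, c(list(t_end, final, params), args))[[1]]
  residual <- max(abs(deriv))
  converged <- residual < 1e-8 * prod_max
  if (!converged)
    warning("terminal state may not be at steady state: max |rhs| = ",
            signif(residual, 3), call. = FALSE)
  attr(final, "residual") <- residual
  attr(final, "converged") <- converged
  final
}

#' Draw a random translation-model parameter set
#'
#' Log-uniform draws spanning \code{decades} decades around the default
#' parameter midpoints, for validation and robustness studies. Draws are
#' rejected (and redrawn) when any analytic relaxation timescale of the
#' model exceeds \code{max_relax_h}: the steady-state protocol integrates a
#' fixed 10000-h horizon, and a parameter set whose slowest eigenmode --
#' notably the filling of a large complexed-miRNA pool at rate
#' \code{alpha_Q}, with timescale
#' \code{(1 + eta_plus*m_T_bar/(eta_minus + beta_TQ))/beta_Q} -- outlives
#' that horizon has no comparable terminal steady state. Uses the current
#' RNG state.
#'
#' @param decades width of the log-uniform band.
#' @param max_relax_h cap on the slowest relaxation timescale (h).
#' @return A [translation_params()] object.
#' @export
random_translation_params <- function(decades = 4, max_relax_h = 600) {
  lu <- function(mid) mid * 10^stats::runif(1, -decades / 2, decades / 2)
  for (i in 1:1000) {
    p <- translation_params(
      n_T = sample(1:3, 1), n_C = sample(1:3, 1),
      alpha_T = lu(10), alpha_C = lu(10), alpha_Q = lu(1),
      beta_T = lu(0.5), beta_C = lu(0.5), beta_Q = lu(0.5),
      lambda_TQ = 1 + lu(10), gamma_T = lu(2), gamma_C = lu(2),
      delta_T = lu(0.3), delta_C = lu(0.3),
      kappa_T = lu(100), kappa_C = lu(100),
      eta_plus = lu(1), eta_minus = lu(1),
      sigma = sample(0:1, 1), r_total = lu(1000))
    ss <- steady_state(p)
    sequester <- p$eta_plus * ss$m_T_bar / (p$eta_minus + beta_TQ(p))
    tau <- max(1 / p$beta_T, 1 / p$beta_C, 1 / p$delta_T, 1 / p$delta_C,
               1 / (p$eta_minus + beta_TQ(p)),
               (1 + sequester) / p$beta_Q)
    if (tau <= max_relax_h) return(p)
  }
  stop("could not draw a parameter set within the relaxation cap",
       call. = FALSE)
}

#' Steady-state sweep over the miRNA binding constant
#'
#' Evaluates the steady-state summary over a grid of miRNA binding
#' constants \code{eta_plus} for one or both target-site locations. The
#' grid stands in for target-site count and affinity: doubling or tripling
#' \code{eta_plus} emulates 2 or 3 target sites. Uses the closed-form
#' steady state of the translation model.
#'
#' @param params a [translation_params()] object (its own \code{eta_plus}
#'   and \code{sigma} are overridden by the grid).
#' @param sigma_values subset of \code{c(0, 1)}; site locations to sweep.
#' @param eta_grid non-negative, strictly increasing grid of binding
#'   constants (1/nM/h). Default: 20 log-spaced points over 1e-2..1e2.
#' @return An object of class \code{"eta_sweep"}: a data frame with one row
#'   per (eta_plus, sigma) pair and the [steady_state()] summary columns.
#' @export
sweep_eta_plus <- function(params, sigma_values = c(0, 1),
                           eta_grid = default_eta_grid()) {
  if (any(eta_grid < 0)) stop("'eta_grid' must be non-negative", call. = FALSE)
  if (length(eta_grid) > 1 && any(diff(eta_grid) <= 0))
    stop("'eta_grid' must be strictly increasing", call. = FALSE)
  if (!all(sigma_values %in% c(0, 1)))
    stop("'sigma_values' must be a subset of c(0, 1)", call. = FALSE)
  rows <- list()
  for (sg in sigma_values) {
    for (eta in eta_grid) {
      ss <- steady_state(set_params(params, sigma = sg, eta_plus = eta))
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(eta_plus = eta, sigma = sg), as.data.frame(ss))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("eta_sweep", "data.frame")
  out
}

#' Default sweep grid for the miRNA binding constant
#'
#' 20 log-spaced points spanning 1e-2 to 1e2 (1/nM/h), bracketing the
#' characteristic values at which the degradation model switches into the
#' queueing regime.
#' @param n number of points.
#' @return A numeric vector.
#' @export
default_eta_grid <- function(n = 20) 10^seq(-2, 2, length.out = n)

#' @export
print.eta_sweep <- function(x, ...) {
  cat(sprintf("eta_plus sweep: %d points x sigma in {%s}\n",
              length(unique(x$eta_plus)),
              paste(sort(unique(x$sigma)), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 4)
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Transcription-halt decay experiment
#'
#' Simulates an in-silico transcription-inhibition (DRB-type) chase on the
#' finite-RNase degradation model. For each miRNA binding constant the
#' system is first integrated to steady state with transcription on; all
#' production rate constants are then set to zero and the decay of the
#' total endogenous mRNA (\code{m_E + s_E}) and total miTarget mRNA
#' (\code{m_T + m_Q + s_T + s_Q}) is recorded at the requested times and
#' normalised to the value at the halt instant.
#'
#' @param params a [degradation_params()] object (its \code{eta_plus} is
#'   overridden per grid value).
#' @param eta_plus_values binding constants to simulate (1/nM/h).
#' @param sample_times sampling times from the halt instant (h); must start
#'   at 0.
#' @param species which total-mRNA profiles to return.
#' @return A list of \code{"decay_profile"} objects (one per species per
#'   eta value), each a list with \code{times}, \code{values} (first value
#'   1), \code{species}, \code{eta_plus}, and the unnormalised initial
#'   abundance \code{m0}.
#' @seealso [detect_decay_phases()], [half_life()]
#' @export
transcription_halt_decay <- function(params,
                                     eta_plus_values = c(0, 1, 2, 4),
                                     sample_times = default_decay_times(),
                                     species = c("endogenous", "miTarget")) {
  species <- match.arg(species, several.ok = TRUE)
  if (sample_times[1] != 0)
    stop("'sample_times' must start at 0 (the halt instant)", call. = FALSE)
  if (any(diff(sample_times) <= 0))
    stop("'sample_times' must be strictly increasing", call. = FALSE)
  profiles <- list()
  for (eta in eta_plus_values) {
    p <- set_params(params, eta_plus = eta)
    ss <- integrate_to_steady_state("degradation", p)
    sol <- deSolve::ode(y = ss, times = sample_times, func = degradation_rhs,
                        parms = p, method = "radau", atol = 1e-9, rtol = 1e-6,
                        transcription_on = FALSE)
    for (sp in species) {
      tot <- if (sp == "endogenous") {
        sol[, "m_E"] + sol[, "s_E"]
      } else {
        sol[, "m_T"] + sol[, "m_Q"] + sol[, "s_T"] + sol[, "s_Q"]
      }
      if (tot[1] <= 0)
        stop("decay profile undefined: zero steady-state abundance of the ",
             sp, " pool", call. = FALSE)
      profiles[[length(profiles) + 1L]] <- structure(
        list(times = as.numeric(sample_times),
             values = as.numeric(tot / tot[1]),
             species = sp, eta_plus = eta, m0 = tot[1]),
        class = "decay_profile")
    }
  }
  profiles
}

#' Default decay sampling times
#'
#' The experimental chase schedule (0, 0.5, 1, 1.5, 2, 3, 4 h) merged with
#' a dense log-ish grid out to \code{t_max} so phase detection has enough
#' support.
#' @param t_max last sample (h).
#' @return Increasing numeric vector starting at 0.
#' @export
default_decay_times <- function(t_max = 12) {
  sort(unique(c(0, 0.5, 1, 1.5, 2, 3, 4,
                seq(0.1, 2, by = 0.1), seq(2.2, t_max, by = 0.2))))
}

#' @export
print.decay_profile <- function(x, ...) {
  cat(sprintf("Decay profile: %s pool, eta_plus = %g (%d samples over %g h)\n",
              x$species, x$eta_plus, length(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.decay_profile <- function(x, ...) {
  data.frame(species = x$species, eta_plus = x$eta_plus,
             time_h = x$times, normalised_value = x$values)
}

#' Effective-rate time series along a decay trajectory
#'
#' Re-simulates the transcription-halt decay for one binding constant and
#' reports the instantaneous effective degradation rates
#' ([effective_degradation_rate()]) and the RNase occupancy split at each
#' sample time. Used to exhibit the queueing mechanism: during the stalled
#' first decay phase the target-derived complexes hold most of the RNase
#' pool and the endogenous effective rate is depressed; it recovers once
#' the target pool is exhausted.
#'
#' @param params a [degradation_params()] object.
#' @param eta_plus binding constant (1/nM/h).
#' @param sample_times times from the halt (h).
#' @return A data frame with columns \code{time_h}, \code{beta_E_eff},
#'   \code{beta_T_eff}, \code{rnase_bound_target_frac},
#'   \code{rnase_bound_endo_frac}, \code{free_rnase}.
#' @export
decay_rate_trace <- function(params, eta_plus,
                             sample_times = default_decay_times()) {
  p <- set_params(params, eta_plus = eta_plus)
  ss <- integrate_to_steady_state("degradation", p)
  sol <- deSolve::ode(y = ss, times = sample_times, func = degradation_rhs,
                      parms = p, method = "radau", atol = 1e-9, rtol = 1e-6,
                      transcription_on = FALSE)
  out <- data.frame(time_h = sol[, "time"])
  n <- nrow(sol)
  be <- bt <- numeric(n)
  for (i in seq_len(n)) {
    st <- pmax(sol[i, -1], 0)
    be[i] <- if (st[["m_E"]] + st[["s_E"]] > 0)
      effective_degradation_rate(st, p, "endogenous") else NA_real_
    tt <- st[["m_T"]] + st[["m_Q"]] + st[["s_T"]] + st[["s_Q"]]
    bt[i] <- if (tt > 0) effective_degradation_rate(st, p, "miTarget") else NA_real_
  }
  out$beta_E_eff <- be
  out$beta_T_eff <- bt
  out$rnase_bound_target_frac <- (sol[, "s_T"] + sol[, "s_Q"]) / p$z_total
  out$rnase_bound_endo_frac <- sol[, "s_E"] / p$z_total
  out$free_rnase <- p$z_total - sol[, "s_T"] - sol[, "s_Q"] - sol[, "s_E"]
  out
}
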