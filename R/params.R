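#' Parameters of the ribosome-competition (translation) model
#'
#' Constructs and validates the parameter set of the two-gene
#' ribosome-competition model: a miRNA-regulated transgene (the
#' \emph{miTarget}) and a constitutively expressed reporter (the
#' \emph{capacity monitor}) drawing on a fixed shared ribosome pool.
#' Concentrations are in nM and time in hours throughout.
#'
#' The miRNA-enhanced mRNA degradation rate is always derived as
#' \code{beta_TQ = lambda_TQ * beta_T} and never stored separately; use
#' [beta_TQ()] to obtain it.
#'
#' @param n_T,n_C gene copy numbers (dimensionless counts).
#' @param alpha_T,alpha_C transcription rate constants per copy (nM/h).
#' @param alpha_Q miRNA production rate constant (nM/h).
#' @param beta_T,beta_C basal mRNA degradation rate constants (1/h).
#' @param beta_Q miRNA degradation rate constant (1/h).
#' @param lambda_TQ fold-increase of miRNA-enhanced degradation
#'   (dimensionless, must exceed 1).
#' @param gamma_T,gamma_C translation rate constants (1/h).
#' @param delta_T,delta_C protein degradation/dilution rate constants (1/h).
#' @param kappa_T,kappa_C effective ribosome--mRNA dissociation constants (nM).
#' @param eta_plus miRNA-to-target-mRNA binding constant (1/nM/h, >= 0).
#' @param eta_minus target:miRNA complex dissociation rate (1/h).
#' @param sigma target-site location switch: 0 = 5'UTR (the bound complex
#'   is not translated and binds no ribosomes), 1 = 3'UTR (the complex is
#'   loaded and translated).
#' @param r_total total ribosome pool (nM).
#'
#' @return An object of class \code{"translation_params"} (a named list).
#' @seealso [degradation_params()], [demand_coefficients()], [steady_state()]
#' @examples
#' p <- translation_params()
#' p$sigma
#' beta_TQ(p)
#' @export
translation_params <- function(n_T = 1, n_C = 1,
                               alpha_T = 80, alpha_C = 30, alpha_Q = 0.002,
                               beta_T = 0.2, beta_C = 0.2, beta_Q = 0.3,
                               lambda_TQ = 20,
                               gamma_T = 2, gamma_C = 2,
                               delta_T = 0.08, delta_C = 0.08,
                               kappa_T = 100, kappa_C = 100,
                               eta_plus = 1, eta_minus = 1,
                               sigma = 1, r_total = 1000) {
  p <- list(n_T = n_T, n_C = n_C,
            alpha_T = alpha_T, alpha_C = alpha_C, alpha_Q = alpha_Q,
            beta_T = beta_T, beta_C = beta_C, beta_Q = beta_Q,
            lambda_TQ = lambda_TQ,
            gamma_T = gamma_T, gamma_C = gamma_C,
            delta_T = delta_T, delta_C = delta_C,
            kappa_T = kappa_T, kappa_C = kappa_C,
            eta_plus = eta_plus, eta_minus = eta_minus,
            sigma = sigma, r_total = r_total)
  validate_translation_params(p)
  structure(p, class = "translation_params")
}

validate_translation_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p)) {
    if (!num1(p[[nm]]))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  strict_pos <- c("n_T", "n_C", "alpha_T", "alpha_C", "alpha_Q",
                  "beta_T", "beta_C", "beta_Q", "gamma_T", "gamma_C",
                  "delta_T", "delta_C", "kappa_T", "kappa_C",
                  "eta_minus", "r_total")
  for (nm in strict_pos) {
    if (p[[nm]] <= 0)
      stop("parameter '", nm, "' must be strictly positive", call. = FALSE)
  }
  if (p$eta_plus < 0) stop("'eta_plus' must be >= 0", call. = FALSE)
  if (p$lambda_TQ <= 1) stop("'lambda_TQ' must exceed 1", call. = FALSE)
  if (!p$sigma %in% c(0, 1)) stop("'sigma' must be 0 or 1", call. = FALSE)
  invisible(p)
}

#' miRNA-enhanced mRNA degradation rate
#'
#' The degradation rate of the miRNA-bound target mRNA,
#' \code{beta_TQ = lambda_TQ * beta_T}. Kept as a derived quantity so the
#' parameter set has a single source of truth.
#'
#' @param params a [translation_params()] object.
#' @return The enhanced degradation rate (1/h).
#' @export
beta_TQ <- function(params) params$lambda_TQ * params$beta_T

#' @export
print.translation_params <- function(x, ...) {
  cat("Ribosome-competition model parameters (nM, h)\n")
  cat(sprintf("  miTarget:  n=%g alpha=%g beta=%g gamma=%g delta=%g kappa=%g\n",
              x$n_T, x$alpha_T, x$beta_T, x$gamma_T, x$delta_T, x$kappa_T))
  cat(sprintf("  monitor:   n=%g alpha=%g beta=%g gamma=%g delta=%g kappa=%g\n",
              x$n_C, x$alpha_C, x$beta_C, x$gamma_C, x$delta_C, x$kappa_C))
  cat(sprintf("  miRNA:     alpha_Q=%g beta_Q=%g eta+=%g eta-=%g lambda_TQ=%g (beta_TQ=%g)\n",
              x$alpha_Q, x$beta_Q, x$eta_plus, x$eta_minus, x$lambda_TQ,
              beta_TQ(x)))
  cat(sprintf("  sigma=%d (%s UTR target sites), r_total=%g nM\n",
              as.integer(x$sigma), if (x$sigma == 1) "3'" else "5'", x$r_total))
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of a parameter object with the named fields replaced and
#' the result re-validated. Convenient for sweeps and design conditions.
#'
#' @param params a [translation_params()] or [degradation_params()] object.
#' @param ... named replacement values.
#' @return A parameter object of the same class.
#' @examples
#' p5 <- set_params(translation_params(), sigma = 0, eta_plus = 3)
#' @export
set_params <- function(params, ...) {
  repl <- list(...)
  unknown <- setdiff(names(repl), names(params))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params[names(repl)] <- repl
  if (inherits(params, "translation_params")) {
    validate_translation_params(params)
  } else {
    validate_degradation_params(params)
  }
  params
}

#' Parameters of the finite-RNase degradation model
#'
#' Constructs and validates the parameter set of the degradation-resource
#' model: the miTarget competes with an endogenous transcript for a finite
#' pool of RNases. mRNAs associate reversibly with free RNase into degrading
#' complexes; catalytic completion consumes the mRNA and releases the RNase
#' (and, for complexes formed from miRNA-bound mRNA, the miRNA). miRNA-driven
#' decay acts by raising the RNase association constant of the bound target
#' from \code{betaT_assoc} to \code{betaTQ_assoc}.
#'
#' Default values place the system in the queueing regime of the two-gene
#' co-expression experiment: an hours-scale endogenous mRNA half-life under
#' no miRNA regulation, and an RNase pool that a strongly transcribed,
#' miRNA-sliced transgene can transiently saturate.
#'
#' @param n_T,n_E copy numbers of the miTarget and the endogenous gene.
#' @param alpha_T,alpha_E transcription rate constants per copy (nM/h).
#' @param alpha_Q miRNA production rate constant (nM/h).
#' @param beta_Q miRNA degradation rate constant (1/h).
#' @param eta_plus,eta_minus miRNA binding/unbinding constants (1/nM/h, 1/h).
#' @param betaT_assoc RNase association constant of free target mRNA (1/nM/h).
#' @param betaTQ_assoc RNase association constant of miRNA-bound target mRNA
#'   (1/nM/h); must be at least \code{betaT_assoc}.
#' @param betaE_assoc RNase association constant of the endogenous mRNA (1/nM/h).
#' @param betaT_dissoc,betaE_dissoc complex dissociation rates (1/h).
#' @param betaT_cat,betaE_cat catalytic completion rates in complex (1/h).
#' @param betaTQ_cat catalytic completion rate of complexes formed from
#'   miRNA-bound target mRNA (1/h). Slower resolution of these complexes is
#'   what lets the sliced target queue on the degradation machinery; with
#'   \code{betaTQ_cat = betaT_cat} the steady-state RNase occupancy becomes
#'   independent of the miRNA binding constant and no queueing arises.
#' @param z_total total RNase pool (nM).
#'
#' @return An object of class \code{"degradation_params"} (a named list).
#' @seealso [translation_params()], [transcription_halt_decay()]
#' @export
degradation_params <- function(n_T = 1, n_E = 1,
                               alpha_T = 100, alpha_E = 10, alpha_Q = 0.025,
                               beta_Q = 0.5,
                               eta_plus = 0, eta_minus = 1,
                               betaT_assoc = 5.5e-4, betaTQ_assoc = 0.4,
                               betaE_assoc = 2.1e-3,
                               betaT_dissoc = 1, betaE_dissoc = 1,
                               betaT_cat = 5, betaTQ_cat = 0.5,
                               betaE_cat = 1,
                               z_total = 250) {
  p <- list(n_T = n_T, n_E = n_E,
            alpha_T = alpha_T, alpha_E = alpha_E, alpha_Q = alpha_Q,
            beta_Q = beta_Q,
            eta_plus = eta_plus, eta_minus = eta_minus,
            betaT_assoc = betaT_assoc, betaTQ_assoc = betaTQ_assoc,
            betaE_assoc = betaE_assoc,
            betaT_dissoc = betaT_dissoc, betaE_dissoc = betaE_dissoc,
            betaT_cat = betaT_cat, betaTQ_cat = betaTQ_cat,
            betaE_cat = betaE_cat,
            z_total = z_total)
  validate_degradation_params(p)
  structure(p, class = "degradation_params")
}

validate_degradation_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p)) {
    if (!num1(p[[nm]]))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  strict_pos <- c("n_T", "n_E", "alpha_T", "alpha_E", "alpha_Q", "beta_Q",
                  "eta_minus", "betaT_assoc", "betaTQ_assoc", "betaE_assoc",
                  "betaT_dissoc", "betaE_dissoc", "betaT_cat", "betaTQ_cat",
                  "betaE_cat", "z_total")
  for (nm in strict_pos) {
    if (p[[nm]] <= 0)
      stop("parameter '", nm, "' must be strictly positive", call. = FALSE)
  }
  if (p$eta_plus < 0) stop("'eta_plus' must be >= 0", call. = FALSE)
  if (p$betaTQ_assoc < p$betaT_assoc)
    stop("'betaTQ_assoc' must be >= 'betaT_assoc' (miRNA-driven decay ",
         "increases the RNase association constant)", call. = FALSE)
  invisible(p)
}

#' @export
print.degradation_params <- function(x, ...) {
  cat("Finite-RNase degradation model parameters (nM, h)\n")
  cat(sprintf("  miTarget:   n=%g alpha=%g assoc=%g (miRNA-bound %g) dissoc=%g cat=%g (miRNA-bound %g)\n",
              x$n_T, x$alpha_T, x$betaT_assoc, x$betaTQ_assoc,
              x$betaT_dissoc, x$betaT_cat, x$betaTQ_cat))
  cat(sprintf("  endogenous: n=%g alpha=%g assoc=%g dissoc=%g cat=%g\n",
              x$n_E, x$alpha_E, x$betaE_assoc, x$betaE_dissoc, x$betaE_cat))
  cat(sprintf("  miRNA:      alpha_Q=%g beta_Q=%g eta+=%g eta-=%g\n",
              x$alpha_Q, x$beta_Q, x$eta_plus, x$eta_minus))
  cat(sprintf("  RNase pool: z_total=%g nM\n", x$z_total))
  invisible(x)
}

# canonical species orderings used by the integrators
TRANSLATION_SPECIES <- c("m_T", "m_Q", "m_C", "q", "p_T", "p_C")
DEGRADATION_SPECIES <- c("m_T", "m_Q", "m_E", "q", "s_T", "s_Q", "s_E")

#' State vector constructors
#'
#' Build named state vectors in the canonical species order of each model.
#' All components must be non-negative and finite.
#'
#' @param m_T,m_Q,m_C,q,p_T,p_C translation-model species (nM): free target
#'   mRNA, target:miRNA complex, monitor mRNA, free miRNA, target protein,
#'   monitor protein.
#' @return A named numeric vector.
#' @export
translation_state <- function(m_T = 0, m_Q = 0, m_C = 0, q = 0,
                              p_T = 0, p_C = 0) {
  s <- c(m_T = m_T, m_Q = m_Q, m_C = m_C, q = q, p_T = p_T, p_C = p_C)
  check_state(s)
  s
}

#' @rdname translation_state
#' @param m_E free endogenous mRNA (nM).
#' @param s_T,s_Q,s_E degrading mRNA:RNase complexes (nM): formed from free
#'   target mRNA, from miRNA-bound target mRNA, and from endogenous mRNA.
#' @export
degradation_state <- function(m_T = 0, m_Q = 0, m_E = 0, q = 0,
                              s_T = 0, s_Q = 0, s_E = 0) {
  s <- c(m_T = m_T, m_Q = m_Q, m_E = m_E, q = q,
         s_T = s_T, s_Q = s_Q, s_E = s_E)
  check_state(s)
  s
}

check_state <- function(s) {
  if (!is.numeric(s) || any(!is.finite(s)))
    stop("state components must be finite numbers", call. = FALSE)
  if (any(s < 0))
    stop("state components must be non-negative", call. = FALSE)
  invisible(s)
}
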