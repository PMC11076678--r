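#' Thalamocortical model parameters
#'
#' Bundles the synaptic, connectivity and sigmoid constants of the
#' three-population thalamocortical neural-mass circuit. Defaults are the
#' standard values of the antecedent thalamocortical model literature.
#'
#' The circuit has three second-order populations: a retinal input stage
#' driven by the exogenous noise process, the excitatory thalamic relay
#' nucleus (TCR), and the inhibitory thalamic reticular nucleus (TRN). TRN
#' inhibits TCR (gain `C2`); TCR excites TRN (gain `C1`); the retinal stage
#' feeds TCR with gain `C3`. Membrane potentials are converted to firing
#' rates by the logistic sigmoid [sigmoid_rate()].
#'
#' Time constants are stated in milliseconds, as conventional; they are
#' converted to seconds once, when the right-hand side is evaluated, so all
#' internal rates are per second.
#'
#' @param H_e Excitatory postsynaptic gain, mV.
#' @param H_i Inhibitory postsynaptic gain, mV.
#' @param tau_e Excitatory synaptic time constant, ms.
#' @param tau_i Inhibitory synaptic time constant, ms. Normally set from the
#'   amyloid load via [tau_inhibitory()]; the default 14.29 ms is the
#'   amyloid-free value (1/S_max).
#' @param nu Sigmoid slope, mV^-1.
#' @param s0 Sigmoid firing threshold, mV.
#' @param e0 Half of the maximum firing rate, s^-1 (maximum rate is `2*e0`).
#' @param C1 TCR-to-TRN excitatory connectivity gain (dimensionless).
#' @param C2 TRN-to-TCR inhibitory connectivity gain (dimensionless).
#' @param C3 Retinal (external excitatory) input gain to TCR (dimensionless).
#' @param mu_r Mean of the exogenous Gaussian white-noise drive, spikes/s;
#'   must lie in \[0, 100\].
#' @param phi_r Variance of the exogenous drive, (spikes/s)^2.
#' @param trn_input Which population drives the TRN sigmoid: `"tcr"` (the
#'   stated circuit, TCR excites TRN; default) or `"trn_self"` (a literal
#'   self-input variant).
#'
#' @return An object of class `"thalabeta_params"`: a validated named list.
#' @seealso [model_derivatives()], [run_repeats()], [tau_inhibitory()]
#' @examples
#' p <- model_parameters()
#' p$tau_i <- tau_inhibitory(2.10)
#' p
#' @export
model_parameters <- function(H_e = 3.25, H_i = 22, tau_e = 10, tau_i = 14.29,
                             nu = 0.56, s0 = 6, e0 = 25,
                             C1 = 35, C2 = 15, C3 = 7,
                             mu_r = 86, phi_r = 1,
                             trn_input = c("tcr", "trn_self")) {
  trn_input <- match.arg(trn_input)
  p <- list(H_e = H_e, H_i = H_i, tau_e = tau_e, tau_i = tau_i,
            nu = nu, s0 = s0, e0 = e0, C1 = C1, C2 = C2, C3 = C3,
            mu_r = mu_r, phi_r = phi_r, trn_input = trn_input)
  class(p) <- "thalabeta_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  num <- p[setdiff(names(p), "trn_input")]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1 &&
                    is.finite(x), logical(1))))
    stop("all model parameters must be finite scalars", call. = FALSE)
  if (p$tau_e <= 0) stop("`tau_e` must be positive", call. = FALSE)
  if (p$tau_i <= 0) stop("`tau_i` must be positive", call. = FALSE)
  if (p$e0 <= 0) stop("`e0` must be positive", call. = FALSE)
  if (p$nu <= 0) stop("`nu` must be positive", call. = FALSE)
  if (p$C1 < 0 || p$C2 < 0 || p$C3 < 0)
    stop("connectivity gains `C1`, `C2`, `C3` must be non-negative",
         call. = FALSE)
  if (p$mu_r < 0 || p$mu_r > 100)
    stop("`mu_r` must lie in [0, 100]", call. = FALSE)
  if (p$phi_r < 0) stop("`phi_r` must be non-negative", call. = FALSE)
  invisible(p)
}

#' @export
print.thalabeta_params <- function(x, ...) {
  cat("Thalamocortical neural-mass parameters\n")
  cat(sprintf("  synaptic gains:   H_e = %.3g mV, H_i = %.3g mV\n",
              x$H_e, x$H_i))
  cat(sprintf("  time constants:   tau_e = %.4g ms, tau_i = %.4g ms\n",
              x$tau_e, x$tau_i))
  cat(sprintf("  sigmoid:          nu = %.3g /mV, s0 = %.3g mV, e0 = %.3g /s\n",
              x$nu, x$s0, x$e0))
  cat(sprintf("  connectivity:     C1 = %.3g, C2 = %.3g, C3 = %.3g (TRN input: %s)\n",
              x$C1, x$C2, x$C3, x$trn_input))
  cat(sprintf("  sensory drive:    mu_r = %.4g sp/s, phi_r = %.3g (sp/s)^2\n",
              x$mu_r, x$phi_r))
  invisible(x)
}

# params as consumed by the compiled core: time constants in seconds
params_for_core <- function(p) {
  list(H_e = p$H_e, H_i = p$H_i,
       tau_e_s = p$tau_e / 1000, tau_i_s = p$tau_i / 1000,
       nu = p$nu, s0 = p$s0, e0 = p$e0,
       C1 = p$C1, C2 = p$C2, C3 = p$C3,
       trn_self = identical(p$trn_input, "trn_self"))
}

#' Neural state vector
#'
#' Constructs the six-dimensional state of the circuit: for each population
#' (retina, TCR, TRN) a potential (mV) and its time derivative (mV/s).
#'
#' @param x_ret1,x_ret2 Retinal population potential and derivative.
#' @param x_tcr1,x_tcr2 Thalamic relay nucleus potential and derivative.
#' @param x_trn1,x_trn2 Thalamic reticular nucleus potential and derivative.
#' @return A named numeric vector of length 6.
#' @examples
#' neural_state()                     # the zero state
#' neural_state(x_ret1 = 1, x_trn1 = 1)
#' @export
neural_state <- function(x_ret1 = 0, x_ret2 = 0, x_tcr1 = 0, x_tcr2 = 0,
                         x_trn1 = 0, x_trn2 = 0) {
  s <- c(x_ret1 = x_ret1, x_ret2 = x_ret2, x_tcr1 = x_tcr1, x_tcr2 = x_tcr2,
         x_trn1 = x_trn1, x_trn2 = x_trn2)
  check_state(s)
  s
}

state_names <- c("x_ret1", "x_ret2", "x_tcr1", "x_tcr2", "x_trn1", "x_trn2")

check_state <- function(state) {
  if (!is.numeric(state) || length(state) != 6)
    stop("a neural state must be a numeric vector of length 6", call. = FALSE)
  if (!all(is.finite(state)))
    stop("invalid neural state: all six entries must be finite",
         call. = FALSE)
  invisible(state)
}

#' Firing-rate sigmoid
#'
#' Converts an average membrane potential into an action-potential pulse
#' density: `S(v) = 2*e0 / (1 + exp(-nu * (v - s0)))`. Strictly increasing,
#' bounded in `(0, 2*e0)`, with `S(s0) = e0`.
#'
#' @param v Membrane potential(s), mV.
#' @param params A [model_parameters()] object.
#' @return Firing rate(s), s^-1, same length as `v`.
#' @examples
#' sigmoid_rate(6, model_parameters())   # half-maximum: 25
#' @export
sigmoid_rate <- function(v, params = model_parameters()) {
  if (!all(is.finite(v)))
    stop("invalid state: membrane potential must be finite", call. = FALSE)
  2 * params$e0 / (1 + exp(-params$nu * (v - params$s0)))
}

#' Time derivatives of the thalamocortical state
#'
#' Evaluates the right-hand side of the three-population system. The retinal
#' stage is a linear second-order synaptic filter of the exogenous drive
#' `p_drive`; TCR is driven by `S(C3*x_ret1 - C2*x_trn1)`; TRN by
#' `S(C1*x_tcr1)` (or the self-input variant, see [model_parameters()]).
#' Each population is a critically damped second-order kernel with a double
#' pole at `-1/tau`.
#'
#' @param state A [neural_state()] vector.
#' @param t Time, s (the autonomous system ignores it; kept for solver
#'   interfaces).
#' @param params A [model_parameters()] object.
#' @param p_drive Exogenous drive value, spikes/s.
#' @return Named numeric vector of the six time derivatives.
#' @examples
#' model_derivatives(neural_state(), 0, model_parameters(), p_drive = 86)
#' @export
model_derivatives <- function(state, t = 0, params = model_parameters(),
                              p_drive = params$mu_r) {
  check_state(state)
  if (!is.finite(p_drive))
    stop("invalid state: `p_drive` must be finite", call. = FALSE)
  d <- .rhs_core(as.numeric(state), p_drive, params_for_core(params))
  names(d) <- state_names
  d
}

#' Model output potential
#'
#' The simulated EEG-like signal: the net input potential to the thalamic
#' relay nucleus, `V = C3*x_ret1 - C2*x_trn1` (retinal excitation minus TRN
#' inhibition), in mV.
#'
#' @param state A [neural_state()] vector, or a matrix with the six state
#'   columns (one row per time point).
#' @param params A [model_parameters()] object.
#' @return The output potential(s), mV.
#' @examples
#' output_potential(neural_state(x_ret1 = 1, x_trn1 = 1))  # 7 - 15 = -8
#' @export
output_potential <- function(state, params = model_parameters()) {
  if (is.matrix(state)) {
    if (ncol(state) != 6 || !all(is.finite(state)))
      stop("state matrix must have six finite columns", call. = FALSE)
    return(params$C3 * state[, 1] - params$C2 * state[, 5])
  }
  check_state(state)
  params$C3 * state[[1]] - params$C2 * state[[5]]
}

#' Noise-free fixed point of the circuit
#'
#' Locates the unique equilibrium of the deterministic system (`phi_r = 0`)
#' at a given constant drive, by scalar root-finding on the TRN potential:
#' the TCR and TRN nullclines reduce to
#' `x_trn1 = H_i*tau_i*S(C1 * H_e*tau_e*S(C3*x_ret1 - C2*x_trn1))` with
#' `x_ret1 = H_e*tau_e*drive`. Used as an independent check of the
#' integrator's long-run behaviour.
#'
#' @param params A [model_parameters()] object.
#' @param drive Constant exogenous drive, spikes/s.
#' @return A [neural_state()] vector at equilibrium.
#' @export
fixed_point <- function(params = model_parameters(), drive = 0) {
  te <- params$tau_e / 1000
  ti <- params$tau_i / 1000
  ret1 <- params$H_e * te * drive
  g <- function(trn1) {
    tcr1 <- params$H_e * te *
      sigmoid_rate(params$C3 * ret1 - params$C2 * trn1, params)
    v_in <- if (identical(params$trn_input, "trn_self"))
      params$C1 * trn1 else params$C1 * tcr1
    params$H_i * ti * sigmoid_rate(v_in, params) - trn1
  }
  hi_max <- params$H_i * ti * 2 * params$e0
  trn1 <- uniroot(g, lower = 0, upper = hi_max + 1, tol = 1e-14)$root
  tcr1 <- params$H_e * te *
    sigmoid_rate(params$C3 * ret1 - params$C2 * trn1, params)
  neural_state(x_ret1 = ret1, x_tcr1 = tcr1, x_trn1 = trn1)
}
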