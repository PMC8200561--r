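#' Boltzmann steady-state parameters
#'
#' Describes the voltage dependence of a gating variable at equilibrium,
#' \eqn{x_\infty(V) = 1/(1 + \exp(\mp (V - V_{1/2})/k))}, with the sign of the
#' exponent set by the orientation: activation curves rise with depolarization,
#' inactivation curves fall.
#'
#' @param v_half Half-maximal voltage \eqn{V_{1/2}} (mV).
#' @param slope_k Slope factor \eqn{k} (mV per e-fold change); must be > 0.
#' @param orientation `"activation"` (monotone increasing in V) or
#'   `"inactivation"` (monotone decreasing).
#' @return An object of class `boltzmann_params`.
#' @examples
#' p <- boltzmann_params(-21.5, 7.2, "activation")
#' steady_state(p, -21.5) # exactly 0.5
#' @export
boltzmann_params <- function(v_half, slope_k,
                             orientation = c("activation", "inactivation")) {
  orientation <- match.arg(orientation)
  if (!is.finite(v_half)) abort("`v_half` must be finite.")
  if (!is.finite(slope_k) || slope_k <= 0) abort("`slope_k` must be > 0.")
  structure(
    list(v_half = as.numeric(v_half), slope_k = as.numeric(slope_k),
         orientation = orientation),
    class = "boltzmann_params"
  )
}

#' Bell-shaped (Gaussian) voltage dependence of a gating time constant
#'
#' \eqn{\tau(V) = \tau_{floor} + (\tau_{peak} - \tau_{floor})
#'   \exp(-((V - V_0)/b)^2)}: maximal at `center_mv`, decaying symmetrically to
#' `floor_ms` far from the center. The additive floor keeps relaxation finite
#' at extreme voltages.
#'
#' @param peak_ms Time constant at the center voltage (ms).
#' @param center_mv Voltage of the peak \eqn{V_0} (mV).
#' @param width_mv Spread \eqn{b} (mV); must be > 0.
#' @param floor_ms Minimum time constant far from the center (ms); >= 0.005.
#' @return An object of class `gaussian_tau_params`.
#' @export
gaussian_tau_params <- function(peak_ms, center_mv, width_mv, floor_ms = 0.005) {
  if (!is.finite(peak_ms) || !is.finite(center_mv) || !is.finite(width_mv) ||
      !is.finite(floor_ms)) {
    abort("All Gaussian tau parameters must be finite.")
  }
  if (floor_ms < 0.005) abort("`floor_ms` must be >= 0.005 ms.")
  if (peak_ms <= floor_ms) abort("`peak_ms` must exceed `floor_ms`.")
  if (width_mv <= 0) abort("`width_mv` must be > 0.")
  structure(
    list(peak_ms = as.numeric(peak_ms), center_mv = as.numeric(center_mv),
         width_mv = as.numeric(width_mv), floor_ms = as.numeric(floor_ms)),
    class = "gaussian_tau_params"
  )
}

#' Steady-state open fraction of a gate
#'
#' @param params A [boltzmann_params()] object.
#' @param v Membrane potential (mV); vectorized.
#' @return Open fraction in (0, 1), same length as `v`.
#' @export
steady_state <- function(params, v) {
  stopifnot(inherits(params, "boltzmann_params"))
  if (any(!is.finite(v))) abort("`v` must be finite.")
  sgn <- if (params$orientation == "activation") -1 else 1
  1 / (1 + exp(sgn * (v - params$v_half) / params$slope_k))
}

#' Voltage-dependent gating time constant
#'
#' @param params A [gaussian_tau_params()] object.
#' @param v Membrane potential (mV); vectorized.
#' @return Time constant (ms), same length as `v`.
#' @export
time_constant <- function(params, v) {
  stopifnot(inherits(params, "gaussian_tau_params"))
  params$floor_ms + (params$peak_ms - params$floor_ms) *
    exp(-((v - params$center_mv) / params$width_mv)^2)
}

#' Specification of one Hodgkin-Huxley gate
#'
#' A gate couples a Boltzmann steady state with a bell-shaped time constant and
#' enters the channel open probability as `x^exponent`. A disabled gate
#' contributes the constant 1 (used for the neutral recovery gate `r`).
#'
#' @param name Gate name, e.g. `"m"`, `"h"`, `"s"`, `"r"`, `"n"`.
#' @param steady A [boltzmann_params()] object.
#' @param tau A [gaussian_tau_params()] object.
#' @param exponent Positive integer power in the open-probability product.
#' @param enabled If `FALSE` the gate is held at 1.
#' @param conductance_boltzmann If `TRUE`, `steady` describes the channel's
#'   *conductance* curve (as measured in voltage clamp) and the gate relaxes to
#'   the `exponent`-th root of the Boltzmann, so that `x_inf^exponent`
#'   reproduces the measured curve. Used for `m` gates with exponent 3.
#' @param tau_hyper_scale Multiplier applied to the time constant at voltages
#'   below `tau$center_mv`; values < 1 model accelerated recovery phenotypes.
#' @return An object of class `gate_spec`.
#' @export
gate_spec <- function(name, steady, tau, exponent = 1L, enabled = TRUE,
                      conductance_boltzmann = FALSE, tau_hyper_scale = 1) {
  stopifnot(inherits(steady, "boltzmann_params"),
            inherits(tau, "gaussian_tau_params"))
  exponent <- as.integer(exponent)
  if (exponent < 1L) abort("`exponent` must be >= 1.")
  if (tau_hyper_scale <= 0) abort("`tau_hyper_scale` must be > 0.")
  structure(
    list(name = name, steady = steady, tau = tau, exponent = exponent,
         enabled = isTRUE(enabled),
         conductance_boltzmann = isTRUE(conductance_boltzmann),
         tau_hyper_scale = as.numeric(tau_hyper_scale)),
    class = "gate_spec"
  )
}

#' Steady-state value toward which a gate relaxes
#'
#' For ordinary gates this is the Boltzmann steady state; for gates flagged
#' `conductance_boltzmann` it is the exponent-th root, so the gating product
#' matches the measured conductance curve at equilibrium. Disabled gates
#' return 1.
#'
#' @inheritParams gate_tau
#' @return Steady-state open fraction, vectorized over `v`.
#' @export
gate_inf <- function(gate, v) {
  stopifnot(inherits(gate, "gate_spec"))
  if (!gate$enabled) return(rep(1, length(v)))
  b <- steady_state(gate$steady, v)
  if (gate$conductance_boltzmann && gate$exponent > 1L) b^(1 / gate$exponent) else b
}

#' Effective time constant of a gate, including recovery scaling
#'
#' @param gate A [gate_spec()] object.
#' @param v Membrane potential (mV); vectorized.
#' @return Time constant (ms).
#' @export
gate_tau <- function(gate, v) {
  stopifnot(inherits(gate, "gate_spec"))
  tau <- time_constant(gate$tau, v)
  if (gate$tau_hyper_scale != 1) {
    hyper <- v < gate$tau$center_mv
    tau[hyper] <- tau[hyper] * gate$tau_hyper_scale
  }
  tau
}

#' Advance gate states by one time step (exact exponential update)
#'
#' Relaxation `dx/dt = (x_inf - x)/tau` integrated exactly over `dt`:
#' `x <- x_inf + (x - x_inf) * exp(-dt/tau)`. Unconditionally stable and keeps
#' every state in [0, 1] for any `dt`.
#'
#' @param state Named numeric vector of gate open fractions.
#' @param v Membrane potential (mV, scalar).
#' @param spec A [gate_spec()] or a [channel_spec()] (all gates advanced).
#' @param dt Time step (ms); must be > 0.
#' @return Updated state vector.
#' @export
gate_step <- function(state, v, spec, dt) {
  if (!is.numeric(dt) || dt <= 0) abort("`dt` must be > 0.")
  validate_gate_state(state)
  gates <- if (inherits(spec, "channel_spec")) spec$gates else list(spec)
  for (g in gates) {
    stopifnot(inherits(g, "gate_spec"))
    if (!g$enabled) next
    if (!g$name %in% names(state)) {
      abort(paste0("State is missing gate '", g$name, "'."))
    }
    xinf <- gate_inf(g, v)
    tau <- gate_tau(g, v)
    state[[g$name]] <- xinf + (state[[g$name]] - xinf) * exp(-dt / tau)
  }
  state
}

#' Closed-form gate trajectory under a voltage clamp
#'
#' At fixed voltage the relaxation has the exact solution
#' `x(t) = x_inf + (x0 - x_inf) exp(-t/tau)`; evaluated on an arbitrary grid.
#'
#' @param gate A [gate_spec()] object.
#' @param v Clamp voltage (mV, scalar).
#' @param x0 Initial open fraction.
#' @param t Time points (ms).
#' @return Open fraction at each `t`.
#' @export
gate_timecourse <- function(gate, v, x0, t) {
  stopifnot(inherits(gate, "gate_spec"))
  if (!gate$enabled) return(rep(1, length(t)))
  xinf <- gate_inf(gate, v)
  xinf + (x0 - xinf) * exp(-t / gate_tau(gate, v))
}

validate_gate_state <- function(state) {
  if (!is.numeric(state) || is.null(names(state))) {
    abort("Gate state must be a named numeric vector.")
  }
  if (any(state < 0 | state > 1)) abort("Gate states must lie in [0, 1].")
  invisible(state)
}
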