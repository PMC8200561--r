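#' Voltage-gated channel specification
#'
#' A channel is a maximum conductance density, a reversal potential, and a set
#' of multiplicative gates; the open probability is the product of the enabled
#' gates raised to their exponents.
#'
#' @param channel_name One of `"NaV1.1"`, `"NaV1.6"`, `"NaV1.7"`, `"NaV1.8"`,
#'   `"KV1"`, `"KV3"`, `"KV4"`, `"KCa"`, `"leak"`.
#' @param gates List of [gate_spec()] objects.
#' @param gbar Maximum conductance density (S/cm^2); >= 0.
#' @param e_rev Reversal potential (mV).
#' @param ttx_sensitive Logical flag (NaV1.8 is TTX-resistant).
#' @param label Optional label distinguishing variants (e.g. mutant name).
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(channel_name, gates, gbar, e_rev,
                         ttx_sensitive = TRUE, label = channel_name) {
  allowed <- c("NaV1.1", "NaV1.6", "NaV1.7", "NaV1.8",
               "KV1", "KV3", "KV4", "KCa", "leak")
  if (!channel_name %in% allowed) {
    abort(paste0("Unknown channel name '", channel_name, "'."))
  }
  if (!is.numeric(gbar) || gbar < 0) abort("`gbar` must be >= 0.")
  stopifnot(all(vapply(gates, inherits, logical(1), "gate_spec")))
  names(gates) <- vapply(gates, `[[`, character(1), "name")
  structure(
    list(channel_name = channel_name, gates = gates, gbar = as.numeric(gbar),
         e_rev = as.numeric(e_rev), ttx_sensitive = isTRUE(ttx_sensitive),
         label = label),
    class = "channel_spec"
  )
}

#' @export
print.channel_spec <- function(x, ...) {
  cat("<channel_spec>", x$label, sprintf("(%s)", x$channel_name), "\n")
  cat("  gbar:", x$gbar, "S/cm^2  e_rev:", x$e_rev, "mV\n")
  for (g in x$gates) {
    cat(sprintf("  gate %s^%d %s: V1/2 = %.1f mV, k = %.2f%s\n",
                g$name, g$exponent, g$steady$orientation,
                g$steady$v_half, g$steady$slope_k,
                if (g$enabled) "" else " (disabled)"))
  }
  invisible(x)
}

#' Gate-state vector at voltage-clamp equilibrium
#'
#' @param spec A [channel_spec()] object.
#' @param v Holding potential (mV, scalar).
#' @return Named numeric vector with one entry per gate (disabled gates at 1).
#' @export
steady_gate_state <- function(spec, v) {
  stopifnot(inherits(spec, "channel_spec"))
  vapply(spec$gates, function(g) gate_inf(g, v), numeric(1))
}

#' Ionic current density through a channel
#'
#' \eqn{I = \bar g \prod_j x_j^{p_j} (V - E_{rev})}; for NaV1.1 this is the
#' familiar \eqn{m^3 h s r \bar g_{Na} (V - E_{Na})}. Disabled gates contribute
#' the constant 1.
#'
#' @param spec A [channel_spec()] object.
#' @param state Named numeric vector of gate open fractions covering every
#'   enabled gate of `spec`.
#' @param v Membrane potential (mV, scalar).
#' @return Current density (mA/cm^2); negative = inward.
#' @export
ionic_current <- function(spec, state, v) {
  stopifnot(inherits(spec, "channel_spec"))
  open <- 1
  for (g in spec$gates) {
    if (!g$enabled) next
    if (!g$name %in% names(state)) {
      abort(paste0("Gate state is missing '", g$name, "' required by ",
                   spec$label, "."), class = "navtrig_config_error")
    }
    open <- open * state[[g$name]]^g$exponent
  }
  # S/cm^2 * mV = mA/cm^2
  spec$gbar * open * (v - spec$e_rev)
}

# --- standard channel library -------------------------------------------------
# Non-NaV1.1 channels: gating values are literature-standard defaults for
# nociceptor axons, frozen after the baseline calibration (the original
# supplementary parameter set is not reproduced here).

nav_gates <- function(act_vh, act_k, h_vh, h_k,
                      tau_m_peak = 0.2, tau_h_peak = 8,
                      tau_m_width = 40, tau_h_width = 70,
                      tau_m_floor = 0.02, tau_h_floor = 3) {
  list(
    gate_spec("m", boltzmann_params(act_vh, act_k, "activation"),
              gaussian_tau_params(tau_m_peak, act_vh, tau_m_width, tau_m_floor),
              exponent = 3L, conductance_boltzmann = TRUE),
    gate_spec("h", boltzmann_params(h_vh, h_k, "inactivation"),
              gaussian_tau_params(tau_h_peak, h_vh, tau_h_width, tau_h_floor))
  )
}

kv_channel <- function(name, gbar, act_vh, act_k, tau_peak, tau_floor,
                       exponent = 4L, e_k = -85) {
  channel_spec(name, list(
    gate_spec("n", boltzmann_params(act_vh, act_k, "activation"),
              gaussian_tau_params(tau_peak, act_vh, 40, tau_floor),
              exponent = exponent)
  ), gbar = gbar, e_rev = e_k)
}

#' Standard (non-NaV1.1) channel models
#'
#' Literature-standard Hodgkin-Huxley reductions of the accompanying channel
#' complement of thin nociceptive fibers: NaV1.6/1.7 (TTX-sensitive, m^3 h),
#' NaV1.8 (TTX-resistant, depolarized activation, with slow inactivation),
#' delayed-rectifier and A-type potassium channels (n^4), and a high-threshold
#' voltage-only reduction of the calcium-activated potassium channel.
#'
#' @param gbar Maximum conductance density (S/cm^2).
#' @param e_na,e_k Reversal potentials (mV).
#' @return A [channel_spec()] object.
#' @name standard_channels
NULL

#' @rdname standard_channels
#' @export
chan_nav16 <- function(gbar = 0.35, e_na = 60) {
  channel_spec("NaV1.6", nav_gates(-26, 7, -65, 7), gbar, e_na)
}

#' @rdname standard_channels
#' @export
chan_nav17 <- function(gbar = 0.22, e_na = 60) {
  channel_spec("NaV1.7", nav_gates(-23, 8, -75, 7), gbar, e_na)
}

#' @rdname standard_channels
#' @export
chan_nav18 <- function(gbar = 0.02, e_na = 60) {
  gates <- nav_gates(-5, 8, -30, 7, tau_m_peak = 0.5, tau_h_peak = 10,
                     tau_m_width = 60, tau_m_floor = 0.08)
  gates <- c(gates, list(
    gate_spec("s", boltzmann_params(-30, 8, "inactivation"),
              gaussian_tau_params(1000, -30, 40, 100))
  ))
  channel_spec("NaV1.8", gates, gbar, e_na, ttx_sensitive = FALSE)
}

#' @rdname standard_channels
#' @export
chan_kv1 <- function(gbar = 0.02, e_k = -85) {
  kv_channel("KV1", gbar, -40, 15, tau_peak = 3, tau_floor = 0.5, e_k = e_k)
}

#' @rdname standard_channels
#' @export
chan_kv3 <- function(gbar = 0.25, e_k = -85) {
  kv_channel("KV3", gbar, -35, 9, tau_peak = 2, tau_floor = 0.5, e_k = e_k)
}

#' @rdname standard_channels
#' @export
chan_kv4 <- function(gbar = 0.03, e_k = -85) {
  kv_channel("KV4", gbar, -45, 12, tau_peak = 2, tau_floor = 0.4, e_k = e_k)
}

#' @rdname standard_channels
#' @export
chan_kca <- function(gbar = 0.04, e_k = -85) {
  channel_spec("KCa", list(
    gate_spec("c", boltzmann_params(-20, 10, "activation"),
              gaussian_tau_params(35, -55, 30, 2))
  ), gbar, e_k)
}
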