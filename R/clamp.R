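#' Simulated voltage-clamp activation curve
#'
#' From rest at the holding potential, the membrane is stepped to each test
#' voltage; gates `m` and `h` relax along their exact exponential trajectories
#' while the slow gates (`s`, `r`) are held at their holding-state values. The
#' peak of the gating product `m^3 h` (times the frozen slow gates) within the
#' step is recorded and the curve is normalized to its global maximum.
#'
#' @param spec A NaV [channel_spec()], e.g. from [load_mutant()].
#' @param v_hold Holding potential (mV).
#' @param steps Test voltages (mV); default -100 to +20 in 10-mV increments.
#' @param step_ms Step duration (ms); the peak is taken within the first 50 ms.
#' @param dt Sampling interval for the closed-form trajectories (ms).
#' @return A tibble with columns `voltage_mv`, `normalized_value`, `protocol`,
#'   `channel_label`.
#' @export
simulate_activation_curve <- function(spec, v_hold = -100,
                                      steps = seq(-100, 20, by = 10),
                                      step_ms = 25, dt = 0.005) {
  stopifnot(inherits(spec, "channel_spec"))
  if (length(steps) == 0) abort("`steps` must be nonempty.")
  hold <- steady_gate_state(spec, v_hold)
  slow_factor <- clamp_slow_factor(spec, hold)
  tgrid <- seq(dt, min(step_ms, 50), by = dt)
  peaks <- vapply(steps, function(v) {
    g <- gate_product_timecourse(spec, v, hold, tgrid, c("m", "h"))
    max(g) * slow_factor
  }, numeric(1))
  tibble(
    voltage_mv = steps,
    normalized_value = peaks / max(peaks),
    protocol = "activation",
    channel_label = spec$label
  )
}

#' Simulated steady-state fast-inactivation (availability) curve
#'
#' Long conditioning pulses set `h` (and `m`) to their steady state at each
#' conditioning voltage; a test pulse then measures the remaining peak gating
#' product, normalized to the most hyperpolarized conditioning step. Slow gates
#' are frozen at the holding value, as conditioning is assumed short relative
#' to slow inactivation.
#'
#' @param spec A NaV [channel_spec()].
#' @param conditioning_steps Conditioning voltages (mV).
#' @param v_test Test-pulse voltage (mV).
#' @param v_hold Holding potential at which the slow gates remain (mV).
#' @param test_ms Test-pulse duration (ms).
#' @param dt Sampling interval (ms).
#' @return A tibble with columns `voltage_mv`, `normalized_value`, `protocol`,
#'   `channel_label`.
#' @export
simulate_inactivation_curve <- function(spec,
                                        conditioning_steps = seq(-100, 20, by = 10),
                                        v_test = -10, v_hold = -100,
                                        test_ms = 10, dt = 0.005) {
  stopifnot(inherits(spec, "channel_spec"))
  if (length(conditioning_steps) == 0) abort("`conditioning_steps` must be nonempty.")
  hold <- steady_gate_state(spec, v_hold)
  tgrid <- seq(dt, test_ms, by = dt)
  peaks <- vapply(conditioning_steps, function(vc) {
    # conditioning >> tau_m, tau_h but << tau_s: fast gates equilibrate at the
    # conditioning voltage, slow gates remain at the holding state
    cond <- steady_gate_state(spec, vc)
    for (nm in setdiff(names(spec$gates), c("m", "h"))) cond[[nm]] <- hold[[nm]]
    g <- gate_product_timecourse(spec, v_test, cond, tgrid, c("m", "h"))
    max(g)
  }, numeric(1))
  tibble(
    voltage_mv = conditioning_steps,
    normalized_value = peaks / max(peaks),
    protocol = "fast_inactivation",
    channel_label = spec$label
  )
}

#' Development of slow inactivation: fitted time constant
#'
#' Reproduces the standard two-pulse protocol: from rest at `v_hold`, the
#' membrane is conditioned at `v_conditioning` for log-spaced durations; after
#' a brief recovery interval at `v_hold` (letting fast inactivation recover
#' while slow inactivation barely moves), a test pulse measures the remaining
#' availability. A single exponential `A exp(-d/tau) + C` is fitted to
#' availability versus conditioning duration and its time constant returned.
#'
#' @param spec A NaV [channel_spec()] with an enabled `s` gate.
#' @param v_conditioning Conditioning voltage (mV); the catalogue reference
#'   voltages are -10, -5 or 0 mV depending on the source study.
#' @param v_hold Holding potential (mV).
#' @param durations Conditioning durations (ms); default 25 log-spaced values
#'   between 50 ms and 12 s.
#' @param recovery_ms Recovery interval at `v_hold` before the test pulse (ms).
#' @param v_test,test_ms,dt Test-pulse voltage, duration and sampling step.
#' @return Fitted time constant (ms), with the availability table attached as
#'   attribute `"data"`.
#' @export
simulate_slow_inactivation_tau <- function(spec, v_conditioning = -10,
                                           v_hold = -80,
                                           durations = 10^seq(log10(50), log10(12000), length.out = 25),
                                           recovery_ms = 20, v_test = 0,
                                           test_ms = 10, dt = 0.005) {
  stopifnot(inherits(spec, "channel_spec"))
  s_gate <- spec$gates[["s"]]
  if (is.null(s_gate) || !s_gate$enabled) {
    abort("Slow-inactivation protocol requires an enabled `s` gate.",
          class = "navtrig_protocol_error")
  }
  hold <- steady_gate_state(spec, v_hold)
  tgrid <- seq(dt, test_ms, by = dt)
  avail <- vapply(durations, function(d) {
    # conditioning phase: every gate relaxes at v_conditioning for d ms
    st <- hold
    for (nm in names(spec$gates)) {
      st[[nm]] <- gate_timecourse(spec$gates[[nm]], v_conditioning, hold[[nm]], d)
    }
    # recovery at v_hold: fast gates recover, slow gate nearly frozen
    for (nm in names(spec$gates)) {
      st[[nm]] <- gate_timecourse(spec$gates[[nm]], v_hold, st[[nm]], recovery_ms)
    }
    g <- gate_product_timecourse(spec, v_test, st, tgrid, c("m", "h"),
                                 frozen = c("s", "r"))
    max(g)
  }, numeric(1))
  avail <- avail / avail[1]
  fit <- fit_single_exponential(durations, avail)
  structure(fit$tau,
            data = tibble(duration_ms = durations, availability = avail),
            fit = fit)
}

#' Steady-state window-current index
#'
#' Numerical integral over V of the overlap of the steady activation
#' (conductance) curve and the fast-inactivation curve,
#' \eqn{\int m_\infty^3(V)\, h_\infty(V)\, dV}, trapezoid rule on a fine grid.
#' A dimensionless area: larger values mean more sustained sodium current at
#' intermediate voltages.
#'
#' @param spec A NaV [channel_spec()] with `m` and `h` gates.
#' @param v_range Integration limits (mV).
#' @param dv Grid spacing (mV); <= 0.5.
#' @return Dimensionless area (mV-weighted overlap).
#' @export
window_current_index <- function(spec, v_range = c(-100, 20), dv = 0.5) {
  stopifnot(inherits(spec, "channel_spec"))
  m <- spec$gates[["m"]]; h <- spec$gates[["h"]]
  if (is.null(m) || is.null(h)) abort("`spec` must have m and h gates.")
  v <- seq(v_range[1], v_range[2], by = dv)
  f <- gate_inf(m, v)^m$exponent * gate_inf(h, v)^h$exponent
  sum((f[-1] + f[-length(f)]) / 2) * dv
}

#' Fit a Boltzmann function to a simulated clamp curve
#'
#' Least-squares fit of `1/(1 + exp(-(V - v_half)/k))` (activation) or the
#' falling orientation (inactivation) to a normalized curve, used for
#' parameter recovery against the catalogue values.
#'
#' @param curve Tibble with `voltage_mv` and `normalized_value` columns, as
#'   returned by the clamp simulators.
#' @param orientation `"activation"` or `"inactivation"`.
#' @return Object of class `boltzmann_fit` with elements `v_half`, `slope_k`,
#'   `orientation`, `fitted`, `residual_sd`.
#' @export
fit_boltzmann <- function(curve, orientation = c("activation", "inactivation")) {
  orientation <- match.arg(orientation)
  v <- curve$voltage_mv; y <- curve$normalized_value
  sgn <- if (orientation == "activation") 1 else -1
  start_vh <- v[which.min(abs(y - 0.5))]
  fit <- minpack.lm::nlsLM(
    y ~ 1 / (1 + exp(-sgn * (v - vh) / k)),
    start = list(vh = start_vh, k = 7),
    lower = c(vh = -150, k = 0.5), upper = c(vh = 60, k = 40),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- coef(fit)
  structure(
    list(v_half = unname(est[["vh"]]), slope_k = unname(est[["k"]]),
         orientation = orientation,
         fitted = unname(stats::fitted(fit)),
         residual_sd = sqrt(mean(stats::resid(fit)^2)),
         data = curve),
    class = "boltzmann_fit"
  )
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit> %s: V1/2 = %.2f mV, k = %.2f mV (rms %.3g)\n",
              x$orientation, x$v_half, x$slope_k, x$residual_sd))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy boltzmann_fit
#' @export
tidy.boltzmann_fit <- function(x, ...) {
  tibble(term = c("v_half", "slope_k"),
         estimate = c(x$v_half, x$slope_k))
}

#' @method glance boltzmann_fit
#' @export
glance.boltzmann_fit <- function(x, ...) {
  tibble(orientation = x$orientation, residual_sd = x$residual_sd,
         n = nrow(x$data))
}

#' Kolmogorov-Smirnov similarity of a simulated curve and its closed form
#'
#' Compares the simulated normalized clamp curve with the closed-form Boltzmann
#' evaluated at the same voltages using the two-sample K-S test, mirroring the
#' similarity criterion used to validate gating curves (p above 0.1 accepted).
#'
#' @param curve Simulated curve tibble (`voltage_mv`, `normalized_value`).
#' @param params The reference [boltzmann_params()].
#' @return A one-row tibble with `d_statistic` and `p_value`.
#' @export
curve_ks_similarity <- function(curve, params) {
  ref <- steady_state(params, curve$voltage_mv)
  res <- suppressWarnings(ks.test(curve$normalized_value, ref))
  tibble(d_statistic = unname(res$statistic), p_value = res$p.value)
}

# product of the named fast gates along their closed-form trajectories,
# times the frozen values of the remaining gates
gate_product_timecourse <- function(spec, v, state0, tgrid, dynamic,
                                    frozen = setdiff(names(spec$gates), dynamic)) {
  g <- rep(1, length(tgrid))
  for (nm in dynamic) {
    gt <- spec$gates[[nm]]
    g <- g * gate_timecourse(gt, v, state0[[nm]], tgrid)^gt$exponent
  }
  for (nm in frozen) {
    gt <- spec$gates[[nm]]
    if (gt$enabled) g <- g * state0[[nm]]^gt$exponent
  }
  g
}

fit_single_exponential <- function(t, y) {
  c0 <- min(y); a0 <- max(y) - c0
  target <- c0 + a0 / exp(1)
  tau0 <- approx(y, t, xout = target, ties = "ordered")$y
  if (!is.finite(tau0)) tau0 <- stats::median(t)
  fit <- minpack.lm::nlsLM(
    y ~ A * exp(-t / tau) + C,
    start = list(A = a0, tau = tau0, C = c0),
    lower = c(A = 0, tau = 1e-3, C = -1),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  est <- coef(fit)
  list(tau = unname(est[["tau"]]), A = unname(est[["A"]]), C = unname(est[["C"]]))
}

clamp_slow_factor <- function(spec, hold) {
  f <- 1
  for (nm in setdiff(names(spec$gates), c("m", "h"))) {
    g <- spec$gates[[nm]]
    if (g$enabled) f <- f * hold[[nm]]^g$exponent
  }
  f
}
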