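#' Generate a jittered agonist release schedule
#'
#' Release events at a base interval with uniform timing jitter, emulating
#' asynchronous transmitter release from mast cells onto the nerve branches.
#' Deterministic given the seed.
#'
#' @param n_events Number of events.
#' @param base_interval_ms Nominal spacing between events (ms).
#' @param jitter_ms Uniform jitter added to each onset, U(0, jitter_ms).
#' @param agonist `"ATP"` or `"5HT"`.
#' @param peak_um Peak concentration per event (uM).
#' @param sites Character vector of terminal names; events cycle over sites.
#' @param t_start_ms Onset of the first event.
#' @param seed Integer seed.
#' @return List of [agonist_event()] objects sorted by onset.
#' @export
gen_release_schedule <- function(n_events = 2, base_interval_ms = 15,
                                 jitter_ms = 0, agonist = "ATP", peak_um = 1,
                                 sites = c("terminal_1", "terminal_2"),
                                 t_start_ms = 20, seed = 1) {
  withr::with_seed(seed, {
    onsets <- t_start_ms + (seq_len(n_events) - 1) * base_interval_ms +
      if (jitter_ms > 0) runif(n_events, 0, jitter_ms) else 0
  })
  onsets <- sort(onsets)
  purrr::imap(as.list(onsets), function(t0, i) {
    agonist_event(agonist = agonist,
                  site = sites[(i - 1) %% length(sites) + 1],
                  t_onset = t0, peak_concentration = peak_um)
  })
}

#' Generate a surrogate "experimental" spike train
#'
#' Renewal-process stand-in for recorded afferent activity: exponential
#' (Poisson) or gamma-distributed inter-spike intervals at a given mean rate.
#' Used to exercise the K-S validation machinery when real recordings are not
#' available; surrogate trains assert statistical behavior, not biological
#' agreement.
#'
#' @param model `"poisson"` or `"gamma"`.
#' @param rate_hz Mean firing rate (Hz).
#' @param shape Gamma shape parameter (ignored for Poisson).
#' @param duration_s Train duration (s).
#' @param seed Integer seed.
#' @return A tibble with columns `fiber_id` (`"surrogate"`) and `t_ms`.
#' @export
gen_surrogate_train <- function(model = c("poisson", "gamma"), rate_hz = 10,
                                shape = 4, duration_s = 10, seed = 1) {
  model <- match.arg(model)
  if (rate_hz <= 0 || duration_s <= 0) abort("Rate and duration must be > 0.")
  n_max <- ceiling(rate_hz * duration_s * 3 + 50)
  withr::with_seed(seed, {
    isi <- if (model == "poisson") {
      rexp(n_max, rate = rate_hz)
    } else {
      rgamma(n_max, shape = shape, rate = shape * rate_hz)
    }
  })
  t_s <- cumsum(isi)
  t_s <- t_s[t_s <= duration_s]
  tibble(fiber_id = "surrogate", t_ms = t_s * 1000)
}

#' Generate a noisy Boltzmann reference curve
#'
#' The closed-form steady-state curve evaluated on the standard clamp voltage
#' grid with additive Gaussian noise, clipped to [0, 1]; a stand-in for
#' digitized experimental gating curves.
#'
#' @param params A [boltzmann_params()] object.
#' @param sd Noise standard deviation (>= 0).
#' @param v_grid Voltages (mV).
#' @param seed Integer seed.
#' @return A tibble with `voltage_mv`, `normalized_value`.
#' @export
gen_noisy_boltzmann <- function(params, sd = 0.02,
                                v_grid = seq(-100, 20, by = 10), seed = 1) {
  if (sd < 0) abort("`sd` must be >= 0.")
  val <- steady_state(params, v_grid)
  if (sd > 0) {
    withr::with_seed(seed, val <- val + rnorm(length(val), 0, sd))
  }
  tibble(voltage_mv = v_grid,
         normalized_value = pmin(pmax(val, 0), 1))
}
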