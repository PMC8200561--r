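#' Replace one gating component of a mutant channel with wild-type values
#'
#' The in-silico "virtual treatment": the Boltzmann *and* time-constant
#' parameters of the chosen component (activation, fast inactivation or slow
#' inactivation) are replaced by the wild-type partner's, leaving the other
#' components untouched. Replacing all three components reproduces the
#' wild-type channel field-by-field.
#'
#' @param mutant,wt NaV1.1 [channel_spec()] objects from [load_mutant()]; they
#'   must come from the same study pair.
#' @param component `"activation"`, `"fast_inactivation"` or
#'   `"slow_inactivation"`.
#' @return The corrected [channel_spec()], labelled
#'   `"<mutant>+<component>_corrected"`.
#' @export
correct_component <- function(mutant, wt,
                              component = c("activation", "fast_inactivation",
                                            "slow_inactivation")) {
  component <- match.arg(component)
  stopifnot(inherits(mutant, "channel_spec"), inherits(wt, "channel_spec"))
  if (is.null(mutant$study) || is.null(wt$study) ||
      !identical(mutant$study, wt$study)) {
    abort("Mutant and WT must come from the same study pair.",
          class = "navtrig_config_error")
  }
  gate <- switch(component, activation = "m", fast_inactivation = "h",
                 slow_inactivation = "s")
  out <- mutant
  out$gates[[gate]] <- wt$gates[[gate]]
  out$label <- paste0(mutant$label, "+", component, "_corrected")
  out
}

#' Evaluate virtual treatments in the combined-agonist scenario
#'
#' Runs the branched-fiber combined ATP + 5-HT experiment for the uncorrected
#' mutant, each requested single-component correction, and the wild-type
#' reference, and tabulates spike counts (ordered by count, ascending).
#'
#' @param mutant Mutant label, e.g. `"L263V"`.
#' @param components Components to test.
#' @param interval_ms Inter-branch release interval (ms).
#' @param config A [sim_config()].
#' @param params Baseline parameters.
#' @return A tibble: `mutant`, `component` (`"none"` for the uncorrected
#'   mutant), `spikes`, `wt_spikes`.
#' @export
evaluate_treatment <- function(mutant,
                               components = c("activation", "fast_inactivation",
                                              "slow_inactivation"),
                               interval_ms = 15, config = sim_config(),
                               params = navtrig_baseline()) {
  wt_label <- wt_partner(mutant)
  wt_chan <- load_mutant(wt_label)
  mut_chan <- load_mutant(mutant)
  count_for <- function(chan) {
    fib <- build_adelta_fiber(mutant, params = params)
    fib <- replace_nav11(fib, chan)
    spike_count(run_combined_scenario(fib, interval_ms, config, params))
  }
  wt_fib <- build_adelta_fiber(wt_label, params = params)
  wt_spikes <- spike_count(run_combined_scenario(wt_fib, interval_ms, config,
                                                 params))
  rows <- list(tibble(mutant = mutant, component = "none",
                      spikes = count_for(mut_chan), wt_spikes = wt_spikes))
  for (comp in components) {
    corrected <- correct_component(mut_chan, wt_chan, comp)
    rows[[length(rows) + 1]] <- tibble(mutant = mutant, component = comp,
                                       spikes = count_for(corrected),
                                       wt_spikes = wt_spikes)
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$spikes)
}

# swap the NaV1.1 channel spec on every placement of a fiber, preserving gbar
replace_nav11 <- function(fiber, chan) {
  for (i in seq_along(fiber$placements)) {
    old <- fiber$placements[[i]]$spec
    if (old$channel_name == "NaV1.1") {
      new <- chan
      new$gbar <- old$gbar
      fiber$placements[[i]]$spec <- new
    }
  }
  fiber
}

# the combined ATP + 5-HT two-branch stimulus used by fig5/fig7 scenarios
run_combined_scenario <- function(fiber, interval_ms, config,
                                  params = navtrig_baseline()) {
  events <- list(
    scenario_event("ATP", "terminal_1", 20, 1, params),
    scenario_event("5HT", "terminal_1", 20, 2, params),
    scenario_event("ATP", "terminal_2", 20 + interval_ms, 1, params),
    scenario_event("5HT", "terminal_2", 20 + interval_ms, 2, params)
  )
  if (is.null(config$duration_ms)) config$duration_ms <- 480
  simulate_fiber(fiber, events, config)
}
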