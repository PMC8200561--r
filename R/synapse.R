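#' An agonist release event at a nerve-terminal compartment
#'
#' @param agonist `"ATP"` or `"5HT"`.
#' @param site Terminal identifier the event acts on (character; must match a
#'   terminal name in the fiber morphology, e.g. `"terminal_1"`).
#' @param t_onset Release time (ms); >= 0.
#' @param peak_concentration Peak free concentration at the terminal (uM).
#' @param mode `"pulse"` (instantaneous rise, exponential diffusional decay) or
#'   `"diffusion"` (point-source 3-D diffusion profile).
#' @param tau_diffusion_ms Diffusional decay time constant for pulse mode (ms).
#' @param distance_um Source-terminal distance for diffusion mode (um).
#' @return An object of class `agonist_event`.
#' @export
agonist_event <- function(agonist = c("ATP", "5HT"), site = "terminal_1",
                          t_onset = 0, peak_concentration = 1,
                          mode = c("pulse", "diffusion"),
                          tau_diffusion_ms = 150, distance_um = 5) {
  agonist <- match.arg(agonist)
  mode <- match.arg(mode)
  if (peak_concentration <= 0) abort("`peak_concentration` must be > 0.")
  if (t_onset < 0) abort("`t_onset` must be >= 0.")
  structure(
    list(agonist = agonist, site = site, t_onset = as.numeric(t_onset),
         peak_concentration = as.numeric(peak_concentration), mode = mode,
         tau_diffusion_ms = as.numeric(tau_diffusion_ms),
         distance_um = as.numeric(distance_um)),
    class = "agonist_event"
  )
}

#' First-order clearance of an extracellular agonist
#'
#' ATP is cleared by partial ecto-enzymatic hydrolysis, 5-HT by a relatively
#' slow transporter uptake; both are modeled as first-order decays on top of
#' diffusion. Defaults give a free-ATP half-life of about 200 ms and a 5-HT
#' half-life of about 2 s.
#'
#' @param mechanism `"hydrolysis"`, `"uptake"` or `"none"`.
#' @param rate First-order rate constant (1/s); forced to 0 when mechanism is
#'   `"none"`.
#' @return An object of class `clearance_spec`.
#' @export
clearance_spec <- function(mechanism = c("hydrolysis", "uptake", "none"),
                           rate = NULL) {
  mechanism <- match.arg(mechanism)
  if (is.null(rate)) {
    rate <- switch(mechanism, hydrolysis = log(2) / 0.2,
                   uptake = log(2) / 2, none = 0)
  }
  if (mechanism == "none") rate <- 0
  if (rate < 0) abort("`rate` must be >= 0.")
  if (mechanism != "none" && rate == 0) mechanism <- "none"
  structure(list(mechanism = mechanism, rate = as.numeric(rate)),
            class = "clearance_spec")
}

#' Default clearance for an agonist
#' @param agonist `"ATP"` or `"5HT"`.
#' @param enabled If `FALSE`, returns the no-clearance specification (used for
#'   the hydrolysis/uptake-removal comparisons).
#' @return A [clearance_spec()].
#' @export
default_clearance <- function(agonist, enabled = TRUE) {
  if (!enabled) return(clearance_spec("none"))
  if (agonist == "ATP") clearance_spec("hydrolysis") else clearance_spec("uptake")
}

#' Extracellular concentration time course of a release event
#'
#' Pulse mode: zero before onset, instantaneous rise to the peak, then decay
#' `exp(-t/tau_diff) * exp(-rate * t)` combining diffusional dilution and
#' first-order clearance. Diffusion mode: the point-source 3-D solution
#' `Q/(4 pi D t)^{3/2} exp(-r^2/(4 D t))` times the clearance factor, rescaled
#' so its maximum equals the event's peak concentration.
#'
#' @param event An [agonist_event()].
#' @param clearance A [clearance_spec()]; default chosen by agonist.
#' @param grid Time grid (ms); must cover the onset.
#' @param diffusion_um2_s Diffusion coefficient for diffusion mode (um^2/s).
#' @param distance_um Source-terminal distance for diffusion mode (um).
#' @return A tibble with `time_ms`, `concentration_um`, `agonist`, `site`
#'   (class `concentration_profile`).
#' @export
concentration_timecourse <- function(event,
                                     clearance = default_clearance(event$agonist),
                                     grid = seq(0, 500, by = 0.1),
                                     diffusion_um2_s = if (event$agonist == "ATP") 300 else 400,
                                     distance_um = event$distance_um %||% 5) {
  stopifnot(inherits(event, "agonist_event"), inherits(clearance, "clearance_spec"))
  if (max(grid) < event$t_onset) {
    abort("Time grid does not cover the event onset.")
  }
  t_rel <- grid - event$t_onset
  rate_per_ms <- clearance$rate / 1000
  conc <- numeric(length(grid))
  on <- t_rel >= 0
  if (event$mode == "pulse") {
    conc[on] <- event$peak_concentration *
      exp(-t_rel[on] / event$tau_diffusion_ms) * exp(-rate_per_ms * t_rel[on])
  } else {
    d_ms <- diffusion_um2_s / 1000 # um^2/ms
    shape <- function(t) {
      out <- numeric(length(t))
      pos <- t > 0
      out[pos] <- (4 * pi * d_ms * t[pos])^(-1.5) *
        exp(-distance_um^2 / (4 * d_ms * t[pos])) * exp(-rate_per_ms * t[pos])
      out
    }
    # rescale against the shape maximum resolved on a fine local grid
    t_star <- distance_um^2 / (6 * d_ms)
    tfine <- seq(t_star / 20, max(t_star * 10, max(t_rel[on]), 1), length.out = 2000)
    peak_shape <- max(shape(tfine))
    conc[on] <- event$peak_concentration * shape(t_rel[on]) / peak_shape
  }
  structure(
    tibble(time_ms = grid, concentration_um = conc,
           agonist = event$agonist, site = event$site),
    class = c("concentration_profile", "tbl_df", "tbl", "data.frame")
  )
}

#' Ligand-gated receptor kinetics (two-gate reduction)
#'
#' Full Markov schemes of P2X3, P2X2 and 5-HT3 receptors are reduced to an
#' activation gate relaxing toward the Hill occupancy of the agonist and a
#' desensitization gate relaxing toward `1 - depth * Hill(C)` with separate
#' onset and recovery time constants. P2X3 desensitizes fast and deeply, P2X2
#' slowly and shallowly, 5-HT3 in between.
#'
#' @param receptor `"P2X3"`, `"P2X2"` or `"5HT3"`.
#' @param ec50 Half-effective concentration (uM).
#' @param hill Hill coefficient.
#' @param tau_activation,tau_desensitization,tau_recovery Gate time constants
#'   (ms).
#' @param desens_depth Maximum fraction of receptors removed by
#'   desensitization at saturating agonist (0..1).
#' @param gmax Maximum conductance density at the terminal (S/cm^2).
#' @param e_rev Reversal potential (mV); nonselective cation, approximately 0.
#' @return An object of class `receptor_spec`.
#' @export
receptor_spec <- function(receptor = c("P2X3", "P2X2", "5HT3"),
                          ec50 = NULL, hill = NULL,
                          tau_activation = NULL, tau_desensitization = NULL,
                          tau_recovery = NULL, desens_depth = NULL,
                          gmax = 0.02, e_rev = 0) {
  receptor <- match.arg(receptor)
  def <- switch(receptor,
    P2X3 = list(ec50 = 1, hill = 1.5, tau_activation = 5,
                tau_desensitization = 100, tau_recovery = 5000,
                desens_depth = 0.97),
    `5HT3` = list(ec50 = 2, hill = 2, tau_activation = 10,
                  tau_desensitization = 2000, tau_recovery = 1000,
                  desens_depth = 0.85),
    P2X2 = list(ec50 = 30, hill = 1.5, tau_activation = 10,
                tau_desensitization = 10000, tau_recovery = 5000,
                desens_depth = 0.5)
  )
  spec <- list(
    receptor = receptor,
    ligand = if (receptor == "5HT3") "5HT" else "ATP",
    ec50 = ec50 %||% def$ec50, hill = hill %||% def$hill,
    tau_activation = tau_activation %||% def$tau_activation,
    tau_desensitization = tau_desensitization %||% def$tau_desensitization,
    tau_recovery = tau_recovery %||% def$tau_recovery,
    desens_depth = desens_depth %||% def$desens_depth,
    gmax = gmax, e_rev = e_rev
  )
  if (spec$ec50 <= 0) abort("`ec50` must be > 0.")
  structure(spec, class = "receptor_spec")
}

#' A mixed receptor population at a terminal
#'
#' @param components List of [receptor_spec()] objects.
#' @param weights Nonnegative weight fractions, summing to 1.
#' @return An object of class `receptor_population`.
#' @export
receptor_population <- function(components, weights) {
  stopifnot(all(vapply(components, inherits, logical(1), "receptor_spec")))
  if (length(weights) != length(components)) {
    abort("One weight per receptor component is required.",
          class = "navtrig_config_error")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    abort("Weights must be nonnegative and sum to 1.")
  }
  structure(list(components = components, weights = as.numeric(weights)),
            class = "receptor_population")
}

#' Default terminal receptor pools
#'
#' Single A-delta fibers carry a pure P2X3 ATP pool plus 5-HT3; the
#' whole-nerve model mixes P2X3/P2X2 at 75/25 as in rodent trigeminal
#' neurons.
#'
#' @param p2x2_fraction Weight of P2X2 in the ATP pool (0 for single-fiber
#'   experiments, 0.25 for the whole nerve).
#' @param gmax_atp,gmax_5ht Terminal conductance densities (S/cm^2) of the ATP
#'   and 5-HT pools.
#' @return A list with elements `ATP` and `5HT`, each a
#'   [receptor_population()].
#' @export
default_receptor_pools <- function(p2x2_fraction = 0, gmax_atp = 0.02,
                                   gmax_5ht = 0.012) {
  atp <- if (p2x2_fraction > 0) {
    receptor_population(
      list(receptor_spec("P2X3", gmax = gmax_atp),
           receptor_spec("P2X2", gmax = gmax_atp)),
      c(1 - p2x2_fraction, p2x2_fraction)
    )
  } else {
    receptor_population(list(receptor_spec("P2X3", gmax = gmax_atp)), 1)
  }
  ht <- receptor_population(list(receptor_spec("5HT3", gmax = gmax_5ht)), 1)
  list(ATP = atp, `5HT` = ht)
}

#' Receptor open fraction driven by a concentration profile
#'
#' Integrates the two-gate reduction along the profile's time grid with exact
#' exponential updates: the activation gate `a` relaxes toward the Hill
#' occupancy with `tau_activation`; the desensitization gate `d` relaxes
#' toward `1 - depth * Hill(C)` with `tau_desensitization` during onset
#' (target below current `d`) and `tau_recovery` otherwise. The open fraction
#' is `a * d`, bounded in [0, 1].
#'
#' @param spec A [receptor_spec()].
#' @param profile A [concentration_timecourse()] tibble whose agonist matches
#'   the receptor's ligand.
#' @return A tibble with `time_ms`, `open_fraction`.
#' @export
receptor_open_fraction <- function(spec, profile) {
  stopifnot(inherits(spec, "receptor_spec"))
  ag <- unique(profile$agonist)
  if (!identical(ag, spec$ligand)) {
    abort(paste0("Profile agonist '", ag, "' does not activate ", spec$receptor, "."),
          class = "navtrig_config_error")
  }
  tt <- profile$time_ms
  occ <- hill_occupancy(profile$concentration_um, spec$ec50, spec$hill)
  n <- length(tt)
  a <- numeric(n); d <- numeric(n)
  a[1] <- 0; d[1] <- 1
  if (n > 1) {
    dt <- diff(tt)
    fa <- exp(-dt / spec$tau_activation)
    for (i in 2:n) {
      a[i] <- occ[i] + (a[i - 1] - occ[i]) * fa[i - 1]
      d_target <- 1 - spec$desens_depth * occ[i]
      tau_d <- if (d_target < d[i - 1]) spec$tau_desensitization else spec$tau_recovery
      d[i] <- d_target + (d[i - 1] - d_target) * exp(-dt[i - 1] / tau_d)
    }
  }
  tibble(time_ms = tt, open_fraction = pmin(pmax(a * d, 0), 1))
}

hill_occupancy <- function(conc, ec50, hill) {
  ch <- conc^hill
  ch / (ch + ec50^hill)
}

#' Generator current of a receptor population
#'
#' Weighted sum of component conductances times the driving force,
#' `sum_i w_i gmax_i open_i(t) (V - E_rev)`; inward (negative) for membrane
#' potentials below the reversal.
#'
#' @param pop A [receptor_population()].
#' @param open_fractions List of open-fraction tibbles, one per component (as
#'   returned by [receptor_open_fraction()]).
#' @param v Membrane potential (mV, scalar).
#' @return A tibble with `time_ms`, `current_ma_cm2`.
#' @export
generator_current <- function(pop, open_fractions, v) {
  stopifnot(inherits(pop, "receptor_population"))
  if (length(open_fractions) != length(pop$components)) {
    abort("One open-fraction series per component is required.",
          class = "navtrig_config_error")
  }
  tt <- open_fractions[[1]]$time_ms
  total <- numeric(length(tt))
  for (i in seq_along(pop$components)) {
    sp <- pop$components[[i]]
    total <- total + pop$weights[i] * sp$gmax *
      open_fractions[[i]]$open_fraction * (v - sp$e_rev)
  }
  tibble(time_ms = tt, current_ma_cm2 = total)
}

#' Terminal conductance time series of a receptor population
#'
#' Conductance-density form of [generator_current()], used to drive the cable
#' model (the driving force is applied implicitly inside the integrator).
#'
#' @inheritParams generator_current
#' @param profile Concentration profile shared by the components.
#' @return A tibble with `time_ms`, `g_s_cm2`, and attribute `e_rev`.
#' @export
population_conductance <- function(pop, profile) {
  stopifnot(inherits(pop, "receptor_population"))
  tt <- profile$time_ms
  g <- numeric(length(tt))
  for (i in seq_along(pop$components)) {
    sp <- pop$components[[i]]
    open <- receptor_open_fraction(sp, profile)$open_fraction
    g <- g + pop$weights[i] * sp$gmax * open
  }
  structure(tibble(time_ms = tt, g_s_cm2 = g),
            e_rev = pop$components[[1]]$e_rev)
}

#' Read a release schedule from a tabular file
#'
#' Columns: `t_onset_ms`, `agonist`, `site`, `peak_um`, `mode`.
#'
#' @param path CSV file path.
#' @return List of [agonist_event()] objects sorted by onset.
#' @export
read_release_schedule <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("t_onset_ms", "agonist", "site", "peak_um", "mode")
  if (!all(needed %in% names(df))) {
    abort(paste("Release schedule must have columns:",
                paste(needed, collapse = ", ")))
  }
  df <- df[order(df$t_onset_ms), ]
  purrr::pmap(df, function(t_onset_ms, agonist, site, peak_um, mode, ...) {
    agonist_event(agonist = agonist, site = site, t_onset = t_onset_ms,
                  peak_concentration = peak_um, mode = mode)
  })
}

#' @rdname read_release_schedule
#' @param events List of [agonist_event()] objects.
#' @export
write_release_schedule <- function(events, path) {
  df <- purrr::map_dfr(events, function(e) {
    tibble(t_onset_ms = e$t_onset, agonist = e$agonist, site = e$site,
           peak_um = e$peak_concentration, mode = e$mode)
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
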