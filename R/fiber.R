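#' Simulation configuration
#'
#' @param dt_ms Integration step (ms); the convergence contract is that spike
#'   counts are invariant under halving of `dt_ms`.
#' @param duration_ms Simulated time (ms); if `NULL`, chosen from the events.
#' @param v_init_mv Initial (resting) potential (mV).
#' @param threshold_mv Spike-detection threshold (upward crossing).
#' @param refractory_ms Minimum separation between detected spikes (ms).
#' @param record Additional compartment kinds to record (`"terminals"` records
#'   every terminal compartment on top of the recording point).
#' @param seed Optional integer seed for stochastic elements.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt_ms = 0.0125, duration_ms = NULL, v_init_mv = -65,
                       threshold_mv = 0, refractory_ms = 1,
                       record = "terminals", seed = NULL) {
  if (dt_ms <= 0) abort("`dt_ms` must be > 0.")
  if (!is.null(duration_ms) && duration_ms <= 0) abort("`duration_ms` must be > 0.")
  structure(
    list(dt_ms = dt_ms, duration_ms = duration_ms, v_init_mv = v_init_mv,
         threshold_mv = threshold_mv, refractory_ms = refractory_ms,
         record = record, seed = seed),
    class = "sim_config"
  )
}

#' Build a model A-delta fiber
#'
#' Populates a branched myelinated morphology with the A-delta channel
#' complement: NaV1.1 (the selected variant), NaV1.6, NaV1.7, a low level of
#' NaV1.8, the potassium channels KV1/KV3/KV4 and KCa at nodes and terminals;
#' internodes are passive with myelin-grade capacitance. Terminals carry the
#' ATP (P2X3, optionally mixed with P2X2) and 5-HT3 receptor pools.
#'
#' @param mutant NaV1.1 variant label from the catalogue (see [load_mutant()]).
#' @param gbar_nav11,gbar_nav16 Nodal conductance densities (S/cm^2); the full
#'   model uses 0.5 and 0.35, knock-down variants 0.35/0.35 and 0.35/0.
#' @param morphology A `fiber_morphology`; default built from the baseline
#'   geometry.
#' @param p2x2_fraction P2X2 weight in the ATP pool (0.25 for the whole-nerve
#'   composition).
#' @param params Baseline parameter list (see [baseline_parameters()]).
#' @param gbar_scale Multiplier on every active conductance (used for
#'   heterogeneity jitter); `0` gives a passive fiber.
#' @param gmax_scale Multiplier on receptor conductances.
#' @return An object of class `fiber_model`.
#' @export
build_adelta_fiber <- function(mutant = "WT_L263V", gbar_nav11 = 0.5,
                               gbar_nav16 = 0.35, morphology = NULL,
                               p2x2_fraction = 0, params = navtrig_baseline(),
                               gbar_scale = 1, gmax_scale = 1) {
  if (gbar_nav11 < 0 || gbar_nav16 < 0) abort("Densities must be nonnegative.")
  geo <- params$geometry
  if (is.null(morphology)) {
    morphology <- branched_morphology(
      n_branches = 2, branch_length_um = geo$branch_length_um,
      stem_length_um = geo$stem_length_um,
      internode_length_um = geo$internode_length_um,
      node_length_um = geo$node_length_um,
      node_diameter_um = geo$node_diameter_um,
      fiber_diameter_um = geo$fiber_diameter_um,
      terminal_length_um = geo$terminal_length_um,
      terminal_diameter_um = geo$terminal_diameter_um,
      terminal_nseg = geo$terminal_nseg
    )
  }
  dens <- params$adelta_densities
  set <- list(
    load_mutant(mutant, gbar = gbar_nav11 * gbar_scale),
    chan_nav16(gbar_nav16 * gbar_scale),
    chan_nav17(dens[["NaV1.7"]] * gbar_scale),
    chan_nav18(dens[["NaV1.8"]] * gbar_scale),
    chan_kv1(dens[["KV1"]] * gbar_scale),
    chan_kv3(dens[["KV3"]] * gbar_scale),
    chan_kv4(dens[["KV4"]] * gbar_scale),
    chan_kca(dens[["KCa"]] * gbar_scale)
  )
  term <- params$terminal
  # nodes carry the fast spike machinery; the adaptation conductance (KCa)
  # lives only at the terminal unless configured otherwise
  node_set <- set
  if (!isTRUE(term$kca_at_nodes)) {
    node_set <- Filter(function(ch) ch$channel_name != "KCa", node_set)
  }
  # terminal complement: scaled-down node channels, but with the dense
  # TTX-resistant NaV1.8 population that sustains firing at the depolarized
  # receptor-driven ending
  term_set <- lapply(set, scale_gbar, term$density_scale)
  for (i in seq_along(term_set)) {
    if (term_set[[i]]$channel_name == "NaV1.8") {
      term_set[[i]]$gbar <- term$nav18_s_cm2 * gbar_scale
    }
  }
  pools <- default_receptor_pools(
    p2x2_fraction = p2x2_fraction,
    gmax_atp = params$receptors$gmax_atp_s_cm2 * gmax_scale,
    gmax_5ht = params$receptors$gmax_5ht_s_cm2 * gmax_scale
  )
  assemble_fiber(morphology, params,
                 node_channels = node_set,
                 terminal_channels = term_set,
                 pools = pools, fiber_class = "Adelta",
                 label = mutant)
}

#' Build a model C fiber
#'
#' Unmyelinated stand-in carrying NaV1.7, NaV1.8 and KV1 (no NaV1.1)
#' throughout, with receptor pools at the distal terminal. Densities are
#' calibrated to fire a small number of spikes per 1 uM ATP event.
#'
#' @inheritParams build_adelta_fiber
#' @export
build_c_fiber <- function(params = navtrig_baseline(), gbar_scale = 1,
                          gmax_scale = 1) {
  cf <- params$c_fiber
  morph <- unmyelinated_morphology(length_um = cf$length_um,
                                   segment_um = cf$segment_um,
                                   diameter_um = cf$diameter_um)
  set <- list(
    chan_nav17(cf$densities[["NaV1.7"]] * gbar_scale),
    chan_nav18(cf$densities[["NaV1.8"]] * gbar_scale),
    chan_kv1(cf$densities[["KV1"]] * gbar_scale),
    chan_kca(cf$densities[["KCa"]] * gbar_scale)
  )
  # like the A-delta ending, the C-fiber terminal is NaV1.8-rich
  term_set <- set
  for (i in seq_along(term_set)) {
    if (term_set[[i]]$channel_name == "NaV1.8") {
      term_set[[i]]$gbar <- cf$nav18_terminal_s_cm2 * gbar_scale
    }
  }
  pools <- default_receptor_pools(
    p2x2_fraction = params$receptors$p2x2_fraction_whole_nerve,
    gmax_atp = cf$gmax_atp_s_cm2 * gmax_scale,
    gmax_5ht = cf$gmax_5ht_s_cm2 * gmax_scale
  )
  fib <- assemble_fiber(morph, params, node_channels = set,
                        terminal_channels = term_set, pools = pools,
                        fiber_class = "C", label = "C")
  fib
}

#' Build an agonist-insensitive fiber
#'
#' Same cable as the C fiber but without receptor pools; contributes no
#' spikes under any agonist.
#'
#' @inheritParams build_adelta_fiber
#' @export
build_inactive_fiber <- function(params = navtrig_baseline(), gbar_scale = 1) {
  fib <- build_c_fiber(params = params, gbar_scale = gbar_scale)
  fib$pools <- list()
  fib$fiber_class <- "inactive"
  fib$label <- "inactive"
  fib
}

scale_gbar <- function(spec, f) {
  spec$gbar <- spec$gbar * f
  spec
}

# Shared fiber assembly: compartment table, axial conductances, channel
# placements, leak reversal balanced so v_init is an exact fixed point.
assemble_fiber <- function(morphology, params, node_channels,
                           terminal_channels, pools, fiber_class, label) {
  validate_morphology(morphology)
  pas <- params$passive
  comp <- as_tibble(morphology)
  comp$area_cm2 <- pi * comp$diameter_um * comp$length_um * 1e-8
  comp$cm_uf_cm2 <- ifelse(comp$kind == "internode", pas$cm_internode_uf_cm2,
                           pas$cm_node_uf_cm2)
  g_leak_node <- if (fiber_class %in% c("C", "inactive") &&
                     !is.null(params$c_fiber$g_leak_s_cm2)) {
    params$c_fiber$g_leak_s_cm2
  } else {
    pas$g_leak_node_s_cm2
  }
  comp$g_leak_s_cm2 <- dplyr::case_when(
    comp$kind == "internode" ~ pas$g_leak_internode_s_cm2,
    comp$kind == "terminal" ~ pas$g_leak_terminal_s_cm2,
    TRUE ~ g_leak_node
  )
  # axial conductance to parent: series of half-compartment resistances (uS)
  half_r <- function(len, diam) {
    area <- pi * (diam / 2)^2 * 1e-8           # cm^2
    pas$ra_ohm_cm * (len / 2 * 1e-4) / area    # Ohm
  }
  g_ax <- numeric(nrow(comp))
  for (i in seq_len(nrow(comp))[-1]) {
    p <- comp$parent_id[i]
    r <- half_r(comp$length_um[i], comp$diameter_um[i]) +
      half_r(comp$length_um[p], comp$diameter_um[p])
    g_ax[i] <- 1e6 / r
  }
  comp$g_axial_us <- g_ax
  placements <- list()
  active_idx <- which(comp$kind == "node")
  term_idx <- which(comp$kind == "terminal")
  for (ch in node_channels) {
    if (ch$gbar > 0) placements[[length(placements) + 1]] <-
        list(spec = ch, comps = active_idx)
  }
  for (ch in terminal_channels) {
    if (ch$gbar > 0) placements[[length(placements) + 1]] <-
        list(spec = ch, comps = term_idx)
  }
  structure(
    list(comp = comp, placements = placements, pools = pools,
         terminals = attr(morphology, "terminals"),
         recording = attr(morphology, "recording"),
         fiber_class = fiber_class, label = label, params = params),
    class = "fiber_model"
  )
}

#' @export
print.fiber_model <- function(x, ...) {
  cat("<fiber_model>", x$label, sprintf("(%s)", x$fiber_class), "\n")
  cat("  compartments:", nrow(x$comp), " terminals:",
      paste(names(x$terminals), collapse = ", "), "\n")
  cat("  channels:", paste(unique(vapply(x$placements, function(p)
    p$spec$label, character(1))), collapse = ", "), "\n")
  invisible(x)
}

# Flatten channel placements into the argument vectors of the C++ integrator.
# Fast gates start at their steady state for v_init; slow inactivation gates
# (name "s") start at their steady state for `slow_init_mv`, carrying the
# rested hyperpolarized history of the fiber (slow inactivation equilibrates
# over tens of seconds, far longer than an inter-trial interval).
flatten_channels <- function(fiber, v_init, slow_init_mv = -80) {
  type_key <- character(0)
  types <- list(v_half = numeric(0), slope_k = numeric(0), act = numeric(0),
                root_exp = numeric(0), tau_peak = numeric(0),
                tau_center = numeric(0), tau_width = numeric(0),
                tau_floor = numeric(0), hyper_scale = numeric(0))
  get_type <- function(g) {
    key <- paste(g$steady$v_half, g$steady$slope_k, g$steady$orientation,
                 g$conductance_boltzmann, g$exponent, g$tau$peak_ms,
                 g$tau$center_mv, g$tau$width_mv, g$tau$floor_ms,
                 g$tau_hyper_scale, sep = "|")
    idx <- match(key, type_key)
    if (is.na(idx)) {
      type_key <<- c(type_key, key)
      types$v_half <<- c(types$v_half, g$steady$v_half)
      types$slope_k <<- c(types$slope_k, g$steady$slope_k)
      types$act <<- c(types$act, as.numeric(g$steady$orientation == "activation"))
      types$root_exp <<- c(types$root_exp,
                           if (g$conductance_boltzmann) g$exponent else 0)
      types$tau_peak <<- c(types$tau_peak, g$tau$peak_ms)
      types$tau_center <<- c(types$tau_center, g$tau$center_mv)
      types$tau_width <<- c(types$tau_width, g$tau$width_mv)
      types$tau_floor <<- c(types$tau_floor, g$tau$floor_ms)
      types$hyper_scale <<- c(types$hyper_scale, g$tau_hyper_scale)
      idx <- length(type_key)
    }
    idx
  }
  chan_comp <- integer(0); chan_gbar <- numeric(0); chan_erev <- numeric(0)
  chan_gstart <- integer(0); chan_ngates <- integer(0)
  gate_type <- integer(0); gate_exp <- integer(0); gate_x0 <- numeric(0)
  area <- fiber$comp$area_cm2
  for (pl in fiber$placements) {
    gates <- Filter(function(g) g$enabled, pl$spec$gates)
    tids <- vapply(gates, get_type, integer(1))
    exps <- vapply(gates, `[[`, integer(1), "exponent")
    x0 <- vapply(gates, function(g)
      gate_inf(g, if (g$name == "s") slow_init_mv else v_init), numeric(1))
    for (ci in pl$comps) {
      chan_comp <- c(chan_comp, ci - 1L)
      chan_gbar <- c(chan_gbar, pl$spec$gbar * area[ci] * 1e6) # S/cm2 -> uS
      chan_erev <- c(chan_erev, pl$spec$e_rev)
      chan_gstart <- c(chan_gstart, length(gate_type))
      chan_ngates <- c(chan_ngates, length(gates))
      gate_type <- c(gate_type, tids - 1L)
      gate_exp <- c(gate_exp, exps)
      gate_x0 <- c(gate_x0, x0)
    }
  }
  list(chan_comp = chan_comp, chan_gbar_us = chan_gbar, chan_erev = chan_erev,
       chan_gate_start = chan_gstart, chan_ngates = chan_ngates,
       gate_type = gate_type, gate_exp = gate_exp, gate_x0 = gate_x0,
       gate_types = as.data.frame(types))
}

# Leak reversal per compartment balancing the resting ionic current, so the
# configured resting potential is an exact fixed point of the dynamics.
balanced_e_leak <- function(fiber, v_init, slow_init_mv = -80) {
  i_dens <- numeric(nrow(fiber$comp))
  for (pl in fiber$placements) {
    st <- steady_gate_state(pl$spec, v_init)
    if ("s" %in% names(st) && pl$spec$gates[["s"]]$enabled) {
      st[["s"]] <- gate_inf(pl$spec$gates[["s"]], slow_init_mv)
    }
    i_dens[pl$comps] <- i_dens[pl$comps] + ionic_current(pl$spec, st, v_init)
  }
  v_init + i_dens / fiber$comp$g_leak_s_cm2
}

#' Simulate a fiber driven by agonist release events
#'
#' Integrates the coupled membrane/gating equations of the compartmental
#' model. Events acting on the same terminal and agonist have their
#' concentration profiles summed before driving the receptor pool; the
#' resulting generator conductance enters only the event's terminal
#' compartment. Returns the voltage trace at the recording point (and
#' terminals) and the detected spike train.
#'
#' @param fiber A [build_adelta_fiber()] / [build_c_fiber()] model.
#' @param events List of [agonist_event()] objects (sites must exist).
#' @param config A [sim_config()].
#' @param clearance_enabled If `FALSE`, ATP hydrolysis and 5-HT uptake are
#'   switched off (the clearance-removal comparison).
#' @param sustained Optional named concentrations (uM), e.g.
#'   `c(ATP = 100, "5HT" = 2)`, applied as constant bath concentrations at
#'   every terminal from `sustained_onset_ms` onward.
#' @param sustained_onset_ms Onset of the sustained application (ms).
#' @param stim Optional list `list(comp =, t_ms =, amp_na =, dur_ms =)` for a
#'   rectangular current injection (used by calibration diagnostics).
#' @return An object of class `fiber_sim`: list with `trace` (tibble
#'   `time_ms`, `v_mv`, `compartment`), `spikes` (tibble `fiber_id`, `t_ms`),
#'   `v_max` per compartment, and the call configuration.
#' @export
simulate_fiber <- function(fiber, events = list(), config = sim_config(),
                           clearance_enabled = TRUE, sustained = NULL,
                           sustained_onset_ms = 0, stim = NULL) {
  stopifnot(inherits(fiber, "fiber_model"), inherits(config, "sim_config"))
  if (inherits(events, "agonist_event")) events <- list(events)
  for (e in events) {
    if (!e$site %in% names(fiber$terminals)) {
      abort(paste0("Event site '", e$site, "' not found in fiber."),
            class = "navtrig_config_error")
    }
  }
  duration <- config$duration_ms %||%
    (max(c(0, vapply(events, `[[`, numeric(1), "t_onset"))) + 300)
  dt <- config$dt_ms
  nsteps <- ceiling(duration / dt)
  tgrid <- seq(0, nsteps) * dt
  syn <- build_generator_conductances(fiber, events, tgrid, clearance_enabled,
                                      sustained, sustained_onset_ms)
  stim_comp <- integer(0)
  stim_mat <- matrix(0, nrow = length(tgrid), ncol = 0)
  if (!is.null(stim)) {
    stim_comp <- as.integer(stim$comp) - 1L
    amp <- ifelse(tgrid >= stim$t_ms & tgrid < stim$t_ms + stim$dur_ms,
                  stim$amp_na, 0)
    stim_mat <- matrix(amp, ncol = 1)
  }
  flat <- flatten_channels(fiber, config$v_init_mv)
  e_leak <- balanced_e_leak(fiber, config$v_init_mv)
  record <- fiber$recording
  if ("terminals" %in% config$record) record <- c(record, unname(fiber$terminals))
  res <- cable_simulate_cpp(
    parent = as.integer(ifelse(is.na(fiber$comp$parent_id), -1L,
                               fiber$comp$parent_id - 1L)),
    c_nf = fiber$comp$cm_uf_cm2 * fiber$comp$area_cm2 * 1e3,
    g_axial_us = fiber$comp$g_axial_us,
    g_leak_us = fiber$comp$g_leak_s_cm2 * fiber$comp$area_cm2 * 1e6,
    e_leak_mv = e_leak,
    chan_comp = flat$chan_comp, chan_gbar_us = flat$chan_gbar_us,
    chan_erev = flat$chan_erev, chan_gate_start = flat$chan_gate_start,
    chan_ngates = flat$chan_ngates, gate_type = flat$gate_type,
    gate_exp = flat$gate_exp, gate_x0 = flat$gate_x0,
    gate_types = flat$gate_types,
    syn_comp = syn$comp - 1L, syn_g_us = syn$g_us, syn_erev = syn$e_rev,
    stim_comp = stim_comp, stim_na = stim_mat,
    dt = dt, nsteps = nsteps, v_init = config$v_init_mv,
    record = as.integer(record) - 1L, record_every = 1L
  )
  comp_names <- c("recording",
                  if ("terminals" %in% config$record) names(fiber$terminals))
  trace <- purrr::map_dfr(seq_along(record), function(i) {
    tibble(time_ms = tgrid, v_mv = res$trace[, i], compartment = comp_names[i])
  })
  rec_trace <- trace[trace$compartment == "recording", c("time_ms", "v_mv")]
  spikes <- detect_spikes(rec_trace, threshold = config$threshold_mv,
                          refractory = config$refractory_ms)
  spikes$fiber_id <- fiber$label
  structure(
    list(trace = trace, spikes = spikes[, c("fiber_id", "t_ms")],
         v_max = res$v_max, fiber = fiber$label, config = config,
         duration_ms = duration),
    class = "fiber_sim"
  )
}

# Per-(site, agonist) generator conductance matrix on the integration grid.
build_generator_conductances <- function(fiber, events, tgrid,
                                         clearance_enabled, sustained,
                                         sustained_onset_ms) {
  cols <- list(); comps <- integer(0); erevs <- numeric(0)
  if (length(fiber$pools)) {
    groups <- list()
    for (e in events) {
      key <- paste(e$site, e$agonist, sep = "|")
      groups[[key]] <- c(groups[[key]], list(e))
    }
    if (!is.null(sustained)) {
      for (ag in names(sustained)) {
        if (sustained[[ag]] <= 0) next
        for (site in names(fiber$terminals)) {
          key <- paste(site, ag, "sustained", sep = "|")
          groups[[key]] <- list(list(sustained_um = sustained[[ag]],
                                     agonist = ag, site = site,
                                     onset = sustained_onset_ms))
        }
      }
    }
    for (key in names(groups)) {
      evs <- groups[[key]]
      ag <- evs[[1]]$agonist
      site <- evs[[1]]$site
      pool <- fiber$pools[[ag]]
      if (is.null(pool)) next
      conc <- numeric(length(tgrid))
      for (e in evs) {
        if (!is.null(e$sustained_um)) {
          conc <- conc + ifelse(tgrid >= e$onset, e$sustained_um, 0)
        } else {
          cl <- default_clearance(ag, enabled = clearance_enabled)
          conc <- conc + concentration_timecourse(e, cl, grid = tgrid)$concentration_um
        }
      }
      profile <- tibble(time_ms = tgrid, concentration_um = conc,
                        agonist = ag, site = site)
      g <- population_conductance(pool, profile)
      ci <- fiber$terminals[[site]]
      cols[[length(cols) + 1]] <- g$g_s_cm2 * fiber$comp$area_cm2[ci] * 1e6
      comps <- c(comps, ci)
      erevs <- c(erevs, attr(g, "e_rev"))
    }
  }
  g_us <- if (length(cols)) do.call(cbind, cols) else
    matrix(0, nrow = length(tgrid), ncol = 0)
  list(comp = comps, g_us = g_us, e_rev = erevs)
}

#' Detect spikes in a voltage trace
#'
#' Upward threshold crossings separated by at least the refractory interval;
#' crossing times are linearly interpolated between samples. Deterministic.
#'
#' @param trace Tibble with `time_ms` and `v_mv`, uniformly sampled.
#' @param threshold Threshold voltage (mV).
#' @param refractory Minimum separation between spikes (ms).
#' @return A tibble with column `t_ms` (strictly increasing).
#' @export
detect_spikes <- function(trace, threshold = 0, refractory = 1) {
  v <- trace$v_mv; tt <- trace$time_ms
  up <- which(v[-length(v)] < threshold & v[-1] >= threshold)
  if (length(up) == 0) return(tibble(t_ms = numeric(0)))
  frac <- (threshold - v[up]) / (v[up + 1] - v[up])
  times <- tt[up] + frac * (tt[up + 1] - tt[up])
  keep <- numeric(0)
  last <- -Inf
  for (ti in times) {
    if (ti - last >= refractory) {
      keep <- c(keep, ti)
      last <- ti
    }
  }
  tibble(t_ms = keep)
}

#' Spike count of a simulation
#' @param sim A `fiber_sim` object.
#' @return Integer spike count at the recording point.
#' @export
spike_count <- function(sim) nrow(sim$spikes)

#' @export
print.fiber_sim <- function(x, ...) {
  cat("<fiber_sim>", x$fiber, sprintf("%.0f ms, %d spikes\n",
                                      x$duration_ms, nrow(x$spikes)))
  invisible(x)
}

#' Smallest inter-event interval allowing both branches to propagate
#'
#' With simultaneous release on both branches, spikes meeting at the branch
#' junction annihilate and the response equals the single-release response;
#' with a sufficient interval, activity from the second branch clears the
#' junction and adds spikes. Returns the smallest tested interval whose
#' response exceeds the simultaneous-release response. For a fiber without a
#' junction (single branch) the interval is irrelevant and the smallest
#' tested value is returned.
#'
#' @param fiber A branched [build_adelta_fiber()] model.
#' @param intervals_ms Candidate intervals (ms), e.g. `c(0, 5, 10, 15)`.
#' @param event_template An [agonist_event()] used for both releases (site is
#'   overridden per branch).
#' @param t0_ms Onset of the first release.
#' @param config A [sim_config()].
#' @return Smallest effective interval (ms), or `NA` if no tested interval
#'   lets the second branch through.
#' @export
min_propagation_interval <- function(fiber, intervals_ms = c(0, 5, 10, 15),
                                     event_template = agonist_event("ATP"),
                                     t0_ms = 20, config = sim_config()) {
  terms <- names(fiber$terminals)
  if (length(terms) < 2) return(min(intervals_ms))
  run_iv <- function(iv) {
    e1 <- event_template; e1$site <- terms[1]; e1$t_onset <- t0_ms
    e2 <- event_template; e2$site <- terms[2]; e2$t_onset <- t0_ms + iv
    spike_count(simulate_fiber(fiber, list(e1, e2), config))
  }
  ivs <- sort(intervals_ms)
  base <- run_iv(ivs[1])
  for (iv in ivs[-1]) {
    if (run_iv(iv) > base) return(iv)
  }
  NA_real_
}
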