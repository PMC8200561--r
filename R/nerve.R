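#' Whole-nerve specification
#'
#' The default composition mirrors the modeled meningeal nerve: five A-delta
#' fibers (carrying the selected NaV1.1 variant), five C fibers and ten
#' agonist-insensitive fibers. Heterogeneity enters as fractional jitter on
#' active conductances and receptor conductances plus asynchronous onset
#' jitter, all seeded.
#'
#' @param n_adelta,n_c,n_inactive Fiber counts.
#' @param mutant NaV1.1 variant of the A-delta fibers.
#' @param heterogeneity Fractional (+/-) jitter on gbar and receptor gmax.
#' @param onset_jitter_ms Uniform per-fiber onset jitter of the sustained
#'   application (ms).
#' @param seed Integer seed.
#' @return An object of class `nerve_spec`.
#' @export
nerve_spec <- function(n_adelta = 5, n_c = 5, n_inactive = 10,
                       mutant = "WT_L263V", heterogeneity = 0.1,
                       onset_jitter_ms = 500, seed = 1) {
  if (any(c(n_adelta, n_c, n_inactive) < 0)) abort("Fiber counts must be >= 0.")
  structure(
    list(n_adelta = n_adelta, n_c = n_c, n_inactive = n_inactive,
         mutant = mutant, heterogeneity = heterogeneity,
         onset_jitter_ms = onset_jitter_ms, seed = seed),
    class = "nerve_spec"
  )
}

#' Build the fiber population of a nerve
#'
#' Deterministic given the spec's seed. A-delta fibers carry the 75/25
#' P2X3/P2X2 ATP pool plus 5-HT3 at their terminals; C fibers lack NaV1.1;
#' inactive fibers carry no receptor pools and never fire under agonists.
#'
#' @param spec A [nerve_spec()].
#' @param params Baseline parameters.
#' @return A list of `fiber_model` objects with unique labels.
#' @export
build_nerve <- function(spec, params = navtrig_baseline()) {
  stopifnot(inherits(spec, "nerve_spec"))
  n_total <- spec$n_adelta + spec$n_c + spec$n_inactive
  jit <- withr::with_seed(spec$seed, {
    matrix(runif(2 * n_total, -spec$heterogeneity, spec$heterogeneity),
           ncol = 2)
  })
  fibers <- vector("list", n_total)
  k <- 0
  for (i in seq_len(spec$n_adelta)) {
    k <- k + 1
    f <- build_adelta_fiber(spec$mutant, p2x2_fraction =
                              params$receptors$p2x2_fraction_whole_nerve,
                            params = params,
                            gbar_scale = 1 + jit[k, 1],
                            gmax_scale = 1 + jit[k, 2])
    f$label <- paste0("Adelta_", i)
    fibers[[k]] <- f
  }
  for (i in seq_len(spec$n_c)) {
    k <- k + 1
    f <- build_c_fiber(params = params, gbar_scale = 1 + jit[k, 1],
                       gmax_scale = 1 + jit[k, 2])
    f$label <- paste0("C_", i)
    fibers[[k]] <- f
  }
  for (i in seq_len(spec$n_inactive)) {
    k <- k + 1
    f <- build_inactive_fiber(params = params, gbar_scale = 1 + jit[k, 1])
    f$label <- paste0("inactive_", i)
    fibers[[k]] <- f
  }
  fibers
}

#' Simulate whole-nerve activity under persistent agonists
#'
#' Every fiber receives the sustained agonist concentrations at its terminals
#' with a per-fiber asynchronous onset (uniform over the spec's jitter window,
#' seeded); spike trains are merged into a single sorted train with fiber
#' identities preserved.
#'
#' @param fibers List of fibers from [build_nerve()].
#' @param atp_um,fiveht_um Sustained concentrations (uM).
#' @param duration_ms Simulated time (ms).
#' @param config A [sim_config()].
#' @param spec The [nerve_spec()] used to build the fibers (for the onset
#'   jitter and seed).
#' @return A list of class `nerve_sim`: `merged` (tibble `fiber_id`, `t_ms`,
#'   sorted), `per_fiber` (named list of spike tibbles), `duration_ms`.
#' @export
simulate_nerve <- function(fibers, atp_um = 100, fiveht_um = 2,
                           duration_ms = 10000, config = sim_config(),
                           spec = nerve_spec()) {
  onsets <- withr::with_seed(spec$seed + 1,
                             runif(length(fibers), 0, spec$onset_jitter_ms))
  config$duration_ms <- duration_ms
  config$record <- character(0) # recording point only; saves memory
  per_fiber <- vector("list", length(fibers))
  names(per_fiber) <- vapply(fibers, `[[`, character(1), "label")
  for (i in seq_along(fibers)) {
    sustained <- c(ATP = atp_um, "5HT" = fiveht_um)
    sustained <- sustained[sustained > 0]
    if (length(fibers[[i]]$pools) == 0 || length(sustained) == 0) {
      per_fiber[[i]] <- tibble(fiber_id = fibers[[i]]$label, t_ms = numeric(0))
      next
    }
    sim <- simulate_fiber(fibers[[i]], events = list(), config = config,
                          sustained = sustained,
                          sustained_onset_ms = onsets[i])
    sp <- sim$spikes
    sp$fiber_id <- fibers[[i]]$label
    per_fiber[[i]] <- sp
  }
  merged <- dplyr::arrange(dplyr::bind_rows(per_fiber), .data$t_ms)
  structure(list(merged = merged, per_fiber = per_fiber,
                 duration_ms = duration_ms),
            class = "nerve_sim")
}

#' @export
print.nerve_sim <- function(x, ...) {
  cat("<nerve_sim>", length(x$per_fiber), "fibers,",
      nrow(x$merged), "spikes over", x$duration_ms, "ms\n")
  invisible(x)
}

#' Summary table of a whole-nerve simulation
#'
#' @param sim A `nerve_sim` object.
#' @return A tibble with one row per fiber plus a `merged` row: spike count,
#'   mean rate, fraction of ISIs below 0.1 s.
#' @export
nerve_summary <- function(sim) {
  stopifnot(inherits(sim, "nerve_sim"))
  rows <- purrr::imap(sim$per_fiber, function(sp, nm) {
    dplyr::mutate(firing_summary(sp, c(0, sim$duration_ms)), fiber_id = nm)
  })
  merged <- dplyr::mutate(firing_summary(sim$merged, c(0, sim$duration_ms)),
                          fiber_id = "merged")
  dplyr::bind_rows(c(rows, list(merged)))[, c("fiber_id", "n_spikes",
                                              "rate_hz",
                                              "fraction_isi_below_100ms")]
}
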