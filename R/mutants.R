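#' The NaV1.1 variant catalogue
#'
#' Biophysical parameters (activation, fast inactivation, slow inactivation
#' Boltzmann midpoints and slopes, plus the slow-inactivation time constant at
#' its reference voltage) for six NaV1.1 variants and the wild-type channel of
#' each source study. Every mutant is paired with the WT characterized in the
#' same publication; the loss-of-function M145T pair has no slow-inactivation
#' data (NA columns). Shipped as a plain CSV so the table is human-readable and
#' round-trips losslessly.
#'
#' @param path CSV file; defaults to the catalogue bundled with the package.
#' @return A tibble with one row per channel variant.
#' @export
load_catalogue <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nav11_catalogue.csv", package = "navtrig")
  }
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname load_catalogue
#' @param catalogue A catalogue tibble, as returned by [load_catalogue()].
#' @export
write_catalogue <- function(catalogue, path) {
  utils::write.csv(catalogue, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Build a NaV1.1 channel model for a catalogued variant
#'
#' Constructs a [channel_spec()] with gates `m` (activation, exponent 3),
#' `h` (fast inactivation), `s` (slow inactivation, absent for the M145T pair)
#' and a neutral recovery gate `r`. Boltzmann parameters come straight from the
#' catalogue row. The `s`-gate time constant is calibrated in closed form so
#' that the simulated slow-inactivation development protocol reproduces the
#' catalogued model time constant at its reference voltage (see
#' [simulate_slow_inactivation_tau()]). Variants reported with accelerated
#' recovery carry a `tau_hyper_scale` < 1 on the hyperpolarized branch of the
#' relevant gate instead of extra kinetic states.
#'
#' @param label Variant label, e.g. `"L263V"` or `"WT_L263V"`.
#' @param gbar Maximum conductance density (S/cm^2); the full fiber model uses
#'   0.5, knock-down experiments 0.35.
#' @param e_na Sodium reversal potential (mV).
#' @param catalogue Catalogue tibble; defaults to the bundled one.
#' @return A [channel_spec()] of channel type `"NaV1.1"` labelled by variant.
#' @export
load_mutant <- function(label, gbar = 0.5, e_na = 60, catalogue = NULL) {
  if (is.null(catalogue)) catalogue <- navtrig_catalogue()
  row <- catalogue[catalogue$label == label, ]
  if (nrow(row) != 1) {
    abort(paste0("Unknown variant label '", label, "'."),
          class = "navtrig_catalogue_error")
  }
  gates <- nav_gates(row$act_vhalf_mv, row$act_k_mv,
                     row$fast_vhalf_mv, row$fast_k_mv,
                     tau_m_peak = 0.15, tau_h_peak = 6)
  if (identical(row$recovery_phenotype, "fast_h")) {
    gates[[2]]$tau_hyper_scale <- 0.5
  }
  has_slow <- is.finite(row$slow_vhalf_mv)
  if (has_slow) {
    s_tau <- calibrate_slow_tau(row$tau_slow_model_ms, row$tau_slow_at_mv,
                                center_mv = row$slow_vhalf_mv)
    s <- gate_spec("s", boltzmann_params(row$slow_vhalf_mv, row$slow_k_mv,
                                         "inactivation"),
                   s_tau,
                   tau_hyper_scale =
                     if (identical(row$recovery_phenotype, "fast_s")) 0.5 else 1)
  } else {
    s <- gate_spec("s", boltzmann_params(-60, 8, "inactivation"),
                   gaussian_tau_params(2000, -60, 40, 50), enabled = FALSE)
  }
  r <- gate_spec("r", boltzmann_params(-60, 8, "inactivation"),
                 gaussian_tau_params(2000, -60, 40, 50), enabled = FALSE)
  out <- channel_spec("NaV1.1", c(gates, list(s, r)), gbar = gbar,
                      e_rev = e_na, label = label)
  out$study <- row$study
  out
}

# Closed-form s-gate tau calibration: choose the Gaussian peak so that
# tau_s(reference voltage) equals the catalogued model value, with the bell
# centered on the slow-inactivation midpoint.
calibrate_slow_tau <- function(target_ms, at_mv, center_mv,
                               width_mv = 40, floor_ms = 50) {
  shape <- exp(-((at_mv - center_mv) / width_mv)^2)
  peak <- floor_ms + (target_ms - floor_ms) / shape
  gaussian_tau_params(peak, center_mv, width_mv, floor_ms)
}

#' Wild-type partner of a catalogued mutant
#'
#' @param label Mutant label, e.g. `"L263V"`.
#' @param catalogue Catalogue tibble; defaults to the bundled one.
#' @return The label of the WT channel characterized in the same study.
#' @export
wt_partner <- function(label, catalogue = NULL) {
  if (is.null(catalogue)) catalogue <- navtrig_catalogue()
  row <- catalogue[catalogue$label == label, ]
  if (nrow(row) != 1) {
    abort(paste0("Unknown variant label '", label, "'."),
          class = "navtrig_catalogue_error")
  }
  wt <- catalogue[catalogue$study == row$study & catalogue$role == "wt", ]
  wt$label
}

# cached bundled catalogue
navtrig_catalogue <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_catalogue()
    cache
  }
})
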