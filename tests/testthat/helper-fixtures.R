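# Shared fixtures. Expensive cable simulations are cached per test run so
# unit tests and acceptance tests can reuse the same results.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# two-branch, two-ATP-release experiment (the branch-interval protocol)
fig4_count <- function(mutant, interval_ms) {
  cached(paste0("fig4_", mutant, "_", interval_ms), {
    x <- run_scenario("fig4_branch_intervals", mutant,
                      interval_ms = interval_ms)
    setNames(x$spikes, x$channel)
  })
}

# combined ATP + 5-HT two-branch experiment
fig5_counts <- function(mutant) {
  cached(paste0("fig5_", mutant), {
    x <- run_scenario("fig5_combined", mutant)
    setNames(x$spikes, x$channel)
  })
}

# 5-HT dose response restricted to the threshold dose
dose_5ht_count <- function(label, dose_um) {
  cached(paste0("dose_", label, "_", dose_um), {
    fib <- build_adelta_fiber(label)
    ev <- agonist_event("5HT", "terminal_1", 20, dose_um,
                        mode = "diffusion", distance_um = 8)
    spike_count(simulate_fiber(fib, list(ev), sim_config(duration_ms = 300)))
  })
}

# small standard fiber for structural tests (short stem/branches, fast)
small_fiber <- function(mutant = "WT_L263V", ...) {
  p <- baseline_parameters()
  p$geometry$stem_length_um <- 3000
  p$geometry$branch_length_um <- 3000
  build_adelta_fiber(mutant, params = p, ...)
}

small_event <- function(site = "terminal_1", t0 = 20, agonist = "ATP",
                        peak = 1) {
  agonist_event(agonist, site, t0, peak, mode = "diffusion", distance_um = 8)
}

# exhaustive two-sample K-S oracle: exact permutation null for the D statistic
ks_permutation_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  d_obs <- suppressWarnings(stats::ks.test(x, y)$statistic)
  count <- 0
  for (j in seq_len(ncol(idx))) {
    a <- pooled[idx[, j]]
    b <- pooled[-idx[, j]]
    d <- suppressWarnings(stats::ks.test(a, b)$statistic)
    if (d >= d_obs - 1e-12) count <- count + 1
  }
  count / ncol(idx)
}
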