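test_that("branched morphology has the stated geometry and one root", {
  m <- branched_morphology()
  expect_equal(sum(is.na(m$parent_id)), 1)
  expect_true(all(m$parent_id[-1] < m$section_id[-1]))
  nodes <- m[m$kind == "node", ]
  expect_true(all(nodes$length_um == 2))
  expect_true(all(nodes$diameter_um == 2))
  expect_true(all(m$diameter_um[m$kind == "internode"] == 5))
  expect_length(attr(m, "terminals"), 2)
  # halving the internode length about doubles the number of active nodes
  m2 <- branched_morphology(internode_length_um = 100)
  expect_gt(sum(m2$kind == "node") / sum(m$kind == "node"), 1.8)
})

test_that("morphology tables round-trip through the flat-file format", {
  m <- branched_morphology(branch_length_um = 2000, stem_length_um = 2000)
  path <- withr::local_tempfile(fileext = ".csv")
  write_morphology(m, path)
  back <- read_morphology(path)
  expect_equal(as.data.frame(back)[, 1:5], as.data.frame(m)[, 1:5])
  expect_equal(unname(attr(back, "recording")), 1L)
})

test_that("detect_spikes finds threshold crossings with a refractory rule", {
  flat <- tibble::tibble(time_ms = seq(0, 50, 0.1), v_mv = -65)
  expect_equal(nrow(detect_spikes(flat)), 0)
  # three synthetic crossings 5 ms apart
  tt <- seq(0, 16, 0.05)
  v <- -65 + 80 * (pmax(0, sin(2 * pi * (tt - 2.5) / 5)))^8
  tr <- tibble::tibble(time_ms = tt, v_mv = v)
  expect_equal(nrow(detect_spikes(tr, threshold = 0, refractory = 1)), 3)
  # two crossings 0.5 ms apart collapse to one under a 1-ms refractory
  tt2 <- seq(0, 3, 0.01)
  v2 <- ifelse((tt2 > 1 & tt2 < 1.2) | (tt2 > 1.5 & tt2 < 1.7), 20, -65)
  expect_equal(nrow(detect_spikes(tibble::tibble(time_ms = tt2, v_mv = v2),
                                  refractory = 1)), 1)
  expect_equal(nrow(detect_spikes(tibble::tibble(time_ms = tt2, v_mv = v2),
                                  refractory = 0.2)), 2)
})

test_that("an unstimulated fiber rests exactly at the configured potential", {
  fib <- small_fiber()
  sim <- simulate_fiber(fib, list(), sim_config(duration_ms = 60))
  expect_equal(nrow(sim$spikes), 0)
  expect_lt(max(abs(sim$trace$v_mv + 65)), 1)
})

test_that("with all active conductances removed a stimulus decays passively", {
  fib <- small_fiber(gbar_scale = 0)
  sim <- simulate_fiber(fib, list(small_event()),
                        sim_config(duration_ms = 150))
  expect_equal(nrow(sim$spikes), 0)
  # the receptor potential stays local and subthreshold at the far end
  rec <- sim$trace$v_mv[sim$trace$compartment == "recording"]
  expect_lt(max(rec), -60)
  term <- sim$trace$v_mv[sim$trace$compartment == "terminal_1"]
  expect_gt(max(term), -60) # but the terminal is depolarized
})

test_that("gain-of-function fibers out-fire their wild type", {
  fib_wt <- small_fiber("WT_L263V")
  fib_mut <- small_fiber("L263V")
  cfg <- sim_config(duration_ms = 300)
  n_wt <- spike_count(simulate_fiber(fib_wt, list(small_event()), cfg))
  n_mut <- spike_count(simulate_fiber(fib_mut, list(small_event()), cfg))
  expect_gte(n_mut, n_wt)
  expect_gt(n_mut, 0)
})

test_that("a propagated spike is preceded by terminal depolarization", {
  fib <- small_fiber("L263V")
  sim <- simulate_fiber(fib, list(small_event()),
                        sim_config(duration_ms = 250))
  expect_gt(nrow(sim$spikes), 0)
  term <- sim$trace[sim$trace$compartment == "terminal_1", ]
  first_spike <- sim$spikes$t_ms[1]
  # suprathreshold excursion at the stimulated terminal before arrival
  expect_gt(max(term$v_mv[term$time_ms < first_spike]), 0)
})

test_that("unknown event sites are rejected", {
  fib <- small_fiber()
  expect_error(simulate_fiber(fib, list(small_event(site = "terminal_9"))),
               class = "navtrig_config_error")
})

test_that("single-branch fibers pass the interval scan trivially", {
  p <- baseline_parameters()
  morph <- branched_morphology(n_branches = 1, branch_length_um = 2000,
                               stem_length_um = 2000,
                               internode_length_um = p$geometry$internode_length_um)
  fib <- build_adelta_fiber("WT_L263V", morphology = morph)
  expect_equal(min_propagation_interval(fib, c(5, 10, 15)), 5)
})
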