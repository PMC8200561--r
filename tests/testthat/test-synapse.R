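test_that("pulse-mode concentration peaks exactly at the event amplitude", {
  ev <- agonist_event("ATP", t_onset = 10, peak_concentration = 1.7)
  prof <- concentration_timecourse(ev, clearance_spec("none"),
                                   grid = seq(0, 200, by = 0.1))
  expect_equal(max(prof$concentration_um), 1.7)
  expect_true(all(prof$concentration_um[prof$time_ms < 10] == 0))
  expect_true(all(prof$concentration_um >= 0))
  expect_error(concentration_timecourse(ev, grid = seq(0, 5, 1)), "onset")
})

test_that("clearance only ever lowers the concentration", {
  ev <- agonist_event("ATP", t_onset = 0, peak_concentration = 1)
  grid <- seq(0, 400, by = 0.1)
  with_h <- concentration_timecourse(ev, default_clearance("ATP"), grid)
  without <- concentration_timecourse(ev, clearance_spec("none"), grid)
  expect_true(all(with_h$concentration_um <= without$concentration_um + 1e-12))
  # ATP hydrolysis half-life default of ~200 ms
  expect_equal(clearance_spec("hydrolysis")$rate, log(2) / 0.2)
})

test_that("doubling the clearance rate halves the decay-tail area", {
  # with a pure first-order tail (diffusion switched off), the area under
  # exp(-r t) is 1/r, so doubling r halves it
  ev <- agonist_event("ATP", t_onset = 0, peak_concentration = 1,
                      tau_diffusion_ms = 1e9)
  grid <- seq(0, 20000, by = 1)
  a1 <- sum(concentration_timecourse(ev, clearance_spec("hydrolysis", 2),
                                     grid)$concentration_um)
  a2 <- sum(concentration_timecourse(ev, clearance_spec("hydrolysis", 4),
                                     grid)$concentration_um)
  expect_equal(a1 / a2, 2, tolerance = 1e-3)
})

test_that("diffusion mode rises, peaks at the event amplitude and decays", {
  ev <- agonist_event("ATP", t_onset = 20, peak_concentration = 1,
                      mode = "diffusion", distance_um = 8)
  prof <- concentration_timecourse(ev, clearance_spec("none"),
                                   grid = seq(0, 600, by = 0.5))
  expect_equal(max(prof$concentration_um), 1, tolerance = 1e-3)
  i_peak <- which.max(prof$concentration_um)
  expect_gt(prof$time_ms[i_peak], 25) # finite rise time
  expect_lt(prof$concentration_um[length(prof$concentration_um)],
            0.5 * max(prof$concentration_um))
})

test_that("receptor gates follow Hill occupancy and desensitize", {
  p2x3 <- receptor_spec("P2X3", hill = 1)
  # zero agonist: open fraction stays zero
  silent <- tibble::tibble(time_ms = seq(0, 100, 0.5), concentration_um = 0,
                           agonist = "ATP", site = "terminal_1")
  expect_true(all(receptor_open_fraction(p2x3, silent)$open_fraction == 0))
  # sustained EC50 with hill 1: activation gate approaches 1/2
  ec <- tibble::tibble(time_ms = seq(0, 2000, 0.5),
                       concentration_um = p2x3$ec50,
                       agonist = "ATP", site = "terminal_1")
  op <- receptor_open_fraction(p2x3, ec)$open_fraction
  a_inf <- 0.5
  d_inf <- 1 - p2x3$desens_depth * 0.5
  expect_equal(op[length(op)], a_inf * d_inf, tolerance = 0.01)
  # saturating ATP: the response peaks then falls below half its peak within
  # five desensitization time constants
  sat <- tibble::tibble(time_ms = seq(0, 5 * p2x3$tau_desensitization, 0.5),
                        concentration_um = 100,
                        agonist = "ATP", site = "terminal_1")
  op2 <- receptor_open_fraction(p2x3, sat)$open_fraction
  expect_lt(op2[length(op2)], 0.5 * max(op2))
  expect_true(all(op2 >= 0 & op2 <= 1))
  # ligand mismatch is a configuration error
  expect_error(receptor_open_fraction(receptor_spec("5HT3"), sat),
               class = "navtrig_config_error")
})

test_that("generator current sums weighted components and reverses at 0 mV", {
  pop <- receptor_population(list(receptor_spec("P2X3", gmax = 0.02),
                                  receptor_spec("P2X2", gmax = 0.02)),
                             c(0.75, 0.25))
  tt <- seq(0, 50, 0.5)
  zeroes <- list(tibble::tibble(time_ms = tt, open_fraction = 0),
                 tibble::tibble(time_ms = tt, open_fraction = 0))
  expect_true(all(generator_current(pop, zeroes, -60)$current_ma_cm2 == 0))
  open <- list(tibble::tibble(time_ms = tt, open_fraction = 0.5),
               tibble::tibble(time_ms = tt, open_fraction = 0.5))
  expect_true(all(generator_current(pop, open, 0)$current_ma_cm2 == 0))
  inward <- generator_current(pop, open, -60)$current_ma_cm2
  expect_true(all(inward < 0))
  expect_equal(inward[1], 0.02 * 0.5 * -60)
  expect_error(generator_current(pop, zeroes[1], -60),
               class = "navtrig_config_error")
})

test_that("the 75/25 P2X3/P2X2 pool outlasts a pure P2X3 pool", {
  # sustained 100 uM ATP: the fast-desensitizing P2X3 component collapses
  # while the P2X2 component persists
  prof <- tibble::tibble(time_ms = seq(0, 2000, 1), concentration_um = 100,
                         agonist = "ATP", site = "terminal_1")
  mixed <- default_receptor_pools(p2x2_fraction = 0.25)
  pure <- default_receptor_pools(p2x2_fraction = 0)
  g_mixed <- population_conductance(mixed$ATP, prof)$g_s_cm2
  g_pure <- population_conductance(pure$ATP, prof)$g_s_cm2
  late <- length(g_mixed)
  expect_gt(g_mixed[late] / max(g_mixed), g_pure[late] / max(g_pure))
})

test_that("release schedules round-trip through the tabular format", {
  evs <- gen_release_schedule(n_events = 3, base_interval_ms = 15,
                              agonist = "ATP", peak_um = 1, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_release_schedule(evs, path)
  back <- read_release_schedule(path)
  expect_equal(length(back), 3)
  expect_equal(vapply(back, `[[`, numeric(1), "t_onset"),
               vapply(evs, `[[`, numeric(1), "t_onset"))
  expect_equal(vapply(back, `[[`, character(1), "site"),
               vapply(evs, `[[`, character(1), "site"))
})
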