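test_that("release schedules are deterministic and correctly spaced", {
  evs <- gen_release_schedule(n_events = 2, base_interval_ms = 10,
                              jitter_ms = 0, t_start_ms = 20, seed = 1)
  expect_equal(vapply(evs, `[[`, numeric(1), "t_onset"), c(20, 30))
  expect_equal(vapply(evs, `[[`, character(1), "site"),
               c("terminal_1", "terminal_2"))
  again <- gen_release_schedule(n_events = 2, base_interval_ms = 10,
                                jitter_ms = 0, t_start_ms = 20, seed = 1)
  expect_identical(evs, again)
  jit1 <- gen_release_schedule(n_events = 5, jitter_ms = 5, seed = 7)
  jit2 <- gen_release_schedule(n_events = 5, jitter_ms = 5, seed = 7)
  expect_identical(jit1, jit2)
})

test_that("uniform onset jitter adds its closed-form mean interval", {
  n <- 10000
  evs <- gen_release_schedule(n_events = n, base_interval_ms = 50,
                              jitter_ms = 5, t_start_ms = 0, seed = 21)
  onsets <- vapply(evs, `[[`, numeric(1), "t_onset")
  added <- onsets - (seq_len(n) - 1) * 50
  # mean of U(0, 5) is 2.5, sd/sqrt(n) gives the CI half-width
  expect_lt(abs(mean(added) - 2.5), 4 * 5 / sqrt(12 * n))
})

test_that("surrogate Poisson trains have the right count statistics", {
  train <- gen_surrogate_train("poisson", rate_hz = 10, duration_s = 100,
                               seed = 5)
  expect_lt(abs(nrow(train) - 1000), 3 * sqrt(1000))
  expect_true(all(diff(train$t_ms) > 0))
  # identical specs and seeds give identical trains, hence K-S p = 1
  t2 <- gen_surrogate_train("poisson", rate_hz = 10, duration_s = 100,
                            seed = 5)
  ks <- ks_two_sample(interspike_intervals(train), interspike_intervals(t2))
  expect_equal(ks$d_statistic, 0)
  expect_equal(ks$p_value, 1)
})

test_that("the K-S test separates gamma from exponential ISIs with power", {
  # gamma(shape 4) at the same mean rate is much more regular than Poisson;
  # at ~500 intervals the test should reject in > 80% of replicates
  rejections <- 0
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    g <- gen_surrogate_train("gamma", rate_hz = 10, shape = 4,
                             duration_s = 50, seed = 1000 + r)
    e <- gen_surrogate_train("poisson", rate_hz = 10, duration_s = 50,
                             seed = 3000 + r)
    p <- ks_two_sample(interspike_intervals(g), interspike_intervals(e))$p_value
    if (p < 0.05) rejections <- rejections + 1
  }
  expect_gt(rejections / n_rep, 0.8)
})

test_that("noisy Boltzmann references behave like their generator", {
  p <- boltzmann_params(-30, 7, "activation")
  clean <- gen_noisy_boltzmann(p, sd = 0)
  expect_equal(clean$normalized_value, steady_state(p, clean$voltage_mv))
  n1 <- gen_noisy_boltzmann(p, sd = 0.05, seed = 2)
  n2 <- gen_noisy_boltzmann(p, sd = 0.05, seed = 2)
  expect_identical(n1, n2)
  expect_true(all(n1$normalized_value >= 0 & n1$normalized_value <= 1))
  # fitting recovers the midpoint within the stochastic tolerance
  withr::with_seed(31, {
    errs <- vapply(1:40, function(i) {
      curve <- gen_noisy_boltzmann(p, sd = 0.02, seed = i)
      names(curve) <- c("voltage_mv", "normalized_value")
      fit_boltzmann(curve, "activation")$v_half - (-30)
    }, numeric(1))
  })
  expect_lt(abs(mean(errs)), 2 * 0.02 * 7)
})
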