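test_that("inter-spike intervals are successive differences in seconds", {
  expect_equal(interspike_intervals(c(10, 30, 70))$isi_s, c(0.02, 0.04))
  expect_equal(nrow(interspike_intervals(c(42))), 0)
  expect_equal(nrow(interspike_intervals(numeric(0))), 0)
  expect_error(interspike_intervals(c(30, 10)), "sorted")
  # merged multi-fiber train: intervals on the sorted union (brute force)
  a <- c(5, 25, 60); b <- c(12, 40)
  merged <- tibble::tibble(t_ms = sort(c(a, b)))
  expect_equal(interspike_intervals(merged)$isi_s,
               diff(sort(c(a, b))) / 1000)
})

test_that("the two-sample K-S test behaves at its extremes", {
  x <- c(0.1, 0.5, 0.9, 1.4)
  same <- ks_two_sample(x, x)
  expect_equal(same$d_statistic, 0)
  expect_equal(same$p_value, 1)
  disjoint <- ks_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(disjoint$d_statistic, 1)
  expect_error(ks_two_sample(numeric(0), x), "nonempty")
  expect_equal(same$n1, 4)
})

test_that("small-sample K-S p-values agree with the permutation oracle", {
  withr::with_seed(11, {
    cases <- list(
      list(x = c(0.12, 0.45, 0.78), y = c(0.2, 0.9, 1.4)),
      list(x = c(1.1, 2.3, 3.1, 4.0), y = c(0.4, 0.9, 1.6)),
      list(x = runif(4), y = runif(5) + 0.3),
      list(x = rexp(5, 3), y = rexp(5, 3))
    )
  })
  for (cs in cases) {
    p_pkg <- ks_two_sample(cs$x, cs$y)$p_value
    p_exact <- ks_permutation_p(cs$x, cs$y)
    expect_lt(abs(p_pkg - p_exact), 0.02)
  }
})

test_that("the K-S statistic is invariant under common monotone transforms", {
  withr::with_seed(3, {
    x <- rexp(40, 5); y <- rgamma(35, 2, 10)
  })
  d0 <- ks_two_sample(x, y)$d_statistic
  expect_equal(ks_two_sample(log(x), log(y))$d_statistic, d0)
  expect_equal(ks_two_sample(sqrt(x), sqrt(y))$d_statistic, d0)
})

test_that("firing summaries count rates and fast-ISI fractions", {
  empty <- firing_summary(numeric(0), window = c(0, 1000))
  expect_equal(empty$n_spikes, 0)
  expect_equal(empty$rate_hz, 0)
  expect_equal(empty$fraction_isi_below_100ms, 0)
  # 11 spikes evenly over one second: 11 Hz; ISIs of exactly 0.1 s are not
  # counted as "faster than 10 Hz" (strict boundary)
  even <- seq(0, 1000, by = 100)
  s <- firing_summary(even, window = c(0, 1000))
  expect_equal(s$n_spikes, 11)
  expect_equal(s$rate_hz, 11)
  expect_equal(s$fraction_isi_below_100ms, 0)
  # Poisson train at 20 Hz: P(ISI < 0.1 s) = 1 - exp(-2)
  train <- gen_surrogate_train("poisson", rate_hz = 20, duration_s = 200,
                               seed = 9)
  frac <- firing_summary(train)$fraction_isi_below_100ms
  p_true <- 1 - exp(-2)
  n <- nrow(train) - 1
  expect_lt(abs(frac - p_true), 4 * sqrt(p_true * (1 - p_true) / n))
})
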