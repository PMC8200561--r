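# a reduced ensemble keeps the whole-nerve tests fast while exercising every
# fiber class
tiny_spec <- function(...) {
  nerve_spec(n_adelta = 2, n_c = 1, n_inactive = 2, seed = 42,
             onset_jitter_ms = 100, ...)
}

tiny_nerve_sim <- function() {
  cached("tiny_nerve", {
    spec <- tiny_spec()
    simulate_nerve(build_nerve(spec), atp_um = 100, fiveht_um = 2,
                   duration_ms = 700, spec = spec)
  })
}

test_that("the nerve has the configured composition", {
  spec <- nerve_spec(seed = 1)
  fibers <- build_nerve(spec)
  expect_length(fibers, 20)
  classes <- vapply(fibers, `[[`, character(1), "fiber_class")
  expect_equal(sum(classes == "Adelta"), 5)
  expect_equal(sum(classes == "C"), 5)
  expect_equal(sum(classes == "inactive"), 10)
  # inactive fibers carry no receptor pools at all
  for (f in fibers[classes == "inactive"]) expect_length(f$pools, 0)
  # A-delta ATP pools mix P2X3/P2X2 at 75/25
  atp <- fibers[[1]]$pools$ATP
  expect_equal(atp$weights, c(0.75, 0.25))
})

test_that("nerve construction is deterministic given the seed", {
  f1 <- build_nerve(nerve_spec(n_adelta = 2, n_c = 1, n_inactive = 1, seed = 9))
  f2 <- build_nerve(nerve_spec(n_adelta = 2, n_c = 1, n_inactive = 1, seed = 9))
  g1 <- vapply(f1, function(f) f$placements[[1]]$spec$gbar, numeric(1))
  g2 <- vapply(f2, function(f) f$placements[[1]]$spec$gbar, numeric(1))
  expect_identical(g1, g2)
  # zero heterogeneity makes all A-delta fibers identical
  f0 <- build_nerve(nerve_spec(n_adelta = 3, n_c = 0, n_inactive = 0,
                               heterogeneity = 0, seed = 5))
  g0 <- vapply(f0, function(f) f$placements[[1]]$spec$gbar, numeric(1))
  expect_true(all(g0 == g0[1]))
})

test_that("the merged train is the exact sorted union of per-fiber trains", {
  sim <- tiny_nerve_sim()
  all_spikes <- sort(unlist(lapply(sim$per_fiber, `[[`, "t_ms")))
  expect_equal(sim$merged$t_ms, unname(all_spikes))
  expect_equal(nrow(sim$merged),
               sum(vapply(sim$per_fiber, nrow, integer(1))))
})

test_that("inactive fibers contribute no spikes; agonists drive the rest", {
  sim <- tiny_nerve_sim()
  summ <- nerve_summary(sim)
  inactive <- summ[grepl("^inactive", summ$fiber_id), ]
  expect_true(all(inactive$n_spikes == 0))
  adelta <- summ[grepl("^Adelta", summ$fiber_id), ]
  expect_true(all(adelta$n_spikes > 0))
})

test_that("without agonists the merged train is empty", {
  spec <- tiny_spec()
  sim <- simulate_nerve(build_nerve(spec), atp_um = 0, fiveht_um = 0,
                        duration_ms = 300, spec = spec)
  expect_equal(nrow(sim$merged), 0)
})

test_that("identical seeds reproduce the merged train exactly", {
  spec <- tiny_spec()
  s1 <- tiny_nerve_sim()
  s2 <- simulate_nerve(build_nerve(spec), atp_um = 100, fiveht_um = 2,
                       duration_ms = 700, spec = spec)
  expect_identical(s1$merged, s2$merged)
})
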