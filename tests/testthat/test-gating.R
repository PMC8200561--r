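test_that("Boltzmann steady state matches its closed form", {
  act <- boltzmann_params(-21.5, 7.2, "activation")
  expect_identical(steady_state(act, -21.5), 0.5)
  expect_equal(steady_state(act, 1e4), 1, tolerance = 1e-12)
  expect_equal(steady_state(boltzmann_params(-21.5, 7.2, "inactivation"), 1e4),
               0, tolerance = 1e-12)
  # frozen high-precision evaluation of 1/(1 + exp(-(v - v_half)/k)) for the
  # L263V activation parameters at -40 mV
  l263v <- boltzmann_params(-24.6, 7.1, "activation")
  expect_equal(steady_state(l263v, -40), 0.10256774905198679,
               tolerance = 1e-14)
  expect_error(steady_state(act, NaN), "finite")
})

test_that("Boltzmann orientations are monotone in the right direction", {
  v <- seq(-100, 20, by = 5)
  act <- steady_state(boltzmann_params(-30, 6, "activation"), v)
  inact <- steady_state(boltzmann_params(-60, 7, "inactivation"), v)
  expect_true(all(diff(act) > 0))
  expect_true(all(diff(inact) < 0))
  expect_true(all(act > 0 & act < 1))
})

test_that("Gaussian time constant is bell-shaped with the stated landmarks", {
  tau <- gaussian_tau_params(peak_ms = 5, center_mv = -40, width_mv = 25,
                             floor_ms = 1)
  expect_identical(time_constant(tau, -40), 5)
  expect_equal(time_constant(tau, -40 + 25), 1 + 4 / exp(1))
  expect_equal(time_constant(tau, -40 - 25), 1 + 4 / exp(1))
  # symmetry about the center for arbitrary offsets
  for (d in c(3, 11.5, 40)) {
    expect_equal(time_constant(tau, -40 + d), time_constant(tau, -40 - d))
  }
  expect_equal(time_constant(tau, 1e4), 1, tolerance = 1e-9)
  expect_error(gaussian_tau_params(0.5, -40, 25, 1), "exceed")
  expect_error(gaussian_tau_params(5, -40, -1, 1), "width")
})

test_that("gate_step is the exact exponential update", {
  g <- gate_spec("m", boltzmann_params(-30, 6, "activation"),
                 gaussian_tau_params(2, -30, 30, 0.5), exponent = 3L)
  v <- -20
  xinf <- gate_inf(g, v)
  tau <- gate_tau(g, v)
  # fixed point
  st <- c(m = xinf)
  expect_equal(gate_step(st, v, g, dt = 7.3)[["m"]], xinf)
  # closed form after one time constant from zero
  st <- c(m = 0)
  expect_equal(gate_step(st, v, g, dt = tau)[["m"]], xinf * (1 - exp(-1)))
  # two half steps compose exactly to one full step
  full <- gate_step(c(m = 0.2), v, g, dt = 1)
  half <- gate_step(gate_step(c(m = 0.2), v, g, dt = 0.5), v, g, dt = 0.5)
  expect_equal(full, half, tolerance = 1e-14)
  expect_error(gate_step(c(m = 0.2), v, g, dt = 0), "dt")
  expect_error(gate_step(c(m = 1.2), v, g, dt = 1), "0, 1")
})

test_that("gate fractions stay in [0, 1] under arbitrary voltage protocols", {
  g <- gate_spec("h", boltzmann_params(-60, 7, "inactivation"),
                 gaussian_tau_params(8, -60, 40, 1))
  withr::with_seed(7, {
    for (rep in 1:20) {
      st <- c(h = runif(1))
      for (step in 1:50) {
        v <- runif(1, -120, 60)
        dt <- 10^runif(1, -2, 1.5)
        st <- gate_step(st, v, g, dt)
        expect_true(st[["h"]] >= 0 && st[["h"]] <= 1)
      }
    }
  })
})

test_that("disabled gates contribute the constant one", {
  g <- gate_spec("r", boltzmann_params(-60, 8, "inactivation"),
                 gaussian_tau_params(2000, -60, 40, 50), enabled = FALSE)
  expect_equal(gate_inf(g, -40), 1)
  expect_equal(gate_timecourse(g, -40, 0.3, c(1, 10, 100)), rep(1, 3))
})
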