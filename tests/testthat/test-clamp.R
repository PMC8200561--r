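test_that("the activation protocol covers -100..20 mV in 10-mV steps", {
  curve <- simulate_activation_curve(load_mutant("WT_L263V"))
  expect_equal(nrow(curve), 13)
  expect_equal(curve$voltage_mv, seq(-100, 20, by = 10))
  expect_equal(max(curve$normalized_value), 1)
  expect_true(all(curve$normalized_value >= 0 & curve$normalized_value <= 1))
  # monotone nondecreasing over the rising limb below the peak
  peak_at <- which.max(curve$normalized_value)
  expect_true(all(diff(curve$normalized_value[1:peak_at]) >= -1e-9))
  expect_named(curve, c("voltage_mv", "normalized_value", "protocol",
                        "channel_label"))
})

test_that("clamp simulations recover the catalogued Boltzmann parameters", {
  tbl <- load_catalogue()
  for (i in seq_len(nrow(tbl))) {
    row <- tbl[i, ]
    ch <- load_mutant(row$label)
    act <- fit_boltzmann(simulate_activation_curve(ch), "activation")
    expect_lt(abs(act$v_half - row$act_vhalf_mv), 2)
    expect_lt(abs(act$slope_k / row$act_k_mv - 1), 0.15)
    inact <- fit_boltzmann(simulate_inactivation_curve(ch), "inactivation")
    expect_lt(abs(inact$v_half - row$fast_vhalf_mv), 2)
    expect_lt(abs(inact$slope_k / row$fast_k_mv - 1), 0.15)
  }
})

test_that("availability curves are monotone and shift with the mutation", {
  wt <- simulate_inactivation_curve(load_mutant("WT_L263V"))
  mut <- simulate_inactivation_curve(load_mutant("L263V"))
  expect_true(all(diff(wt$normalized_value) <= 1e-9))
  expect_equal(max(wt$normalized_value), 1)
  # L263V fast inactivation sits right of its WT (-54.4 vs -62.2 mV), so at
  # mid voltages the mutant retains more availability
  mid <- wt$voltage_mv %in% c(-70, -60, -50)
  expect_true(all(mut$normalized_value[mid] > wt$normalized_value[mid]))
})

test_that("a constant slow-inactivation tau is recovered by the protocol", {
  ch <- load_mutant("L263V")
  # flatten the s-gate tau surface to an (almost) constant 1500 ms
  ch$gates$s$tau <- gaussian_tau_params(1500, -50, 1e4, 1499)
  tau <- simulate_slow_inactivation_tau(ch, v_conditioning = -10)
  expect_equal(as.numeric(tau), 1500, tolerance = 0.01)
  nos <- load_mutant("WT_M145T")
  expect_error(simulate_slow_inactivation_tau(nos),
               class = "navtrig_protocol_error")
})

test_that("the window-current overlap is larger for L263V than its WT", {
  w_mut <- window_current_index(load_mutant("L263V"))
  w_wt <- window_current_index(load_mutant("WT_L263V"))
  expect_gt(w_mut, w_wt)
  # absorbing zero: availability identically zero gives zero area
  ch <- load_mutant("L263V")
  ch$gates$h$steady <- boltzmann_params(-500, 1, "inactivation")
  expect_equal(window_current_index(ch), 0, tolerance = 1e-6)
  # grid refinement changes the integral by < 1e-3 relative
  a <- window_current_index(load_mutant("L263V"), dv = 0.5)
  b <- window_current_index(load_mutant("L263V"), dv = 0.25)
  expect_lt(abs(a / b - 1), 1e-3)
})

test_that("simulated gating curves are K-S-similar to their closed forms", {
  tbl <- load_catalogue()
  for (lab in tbl$label) {
    ch <- load_mutant(lab)
    ks <- curve_ks_similarity(simulate_activation_curve(ch), ch$gates$m$steady)
    expect_gt(ks$p_value, 0.1)
  }
})

test_that("tidy and glance summarize a Boltzmann fit", {
  fit <- fit_boltzmann(simulate_activation_curve(load_mutant("L263V")),
                       "activation")
  td <- tidy(fit)
  expect_equal(td$term, c("v_half", "slope_k"))
  gl <- glance(fit)
  expect_equal(gl$n, 13)
  expect_lt(gl$residual_sd, 0.05)
})
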