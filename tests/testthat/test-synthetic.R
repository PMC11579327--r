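test_that("noise-free degenerate scenarios reproduce exact mixtures", {
  # no noise, literature means, f = 1: observed NO2 equals the exact mixture
  sim <- simulate_campaign(toy_scenario())
  expected <- mix_delta(c(10, 4, 5), c(-2.5, -16.5, -33.2))
  expect_equal(sim$samples$delta_no2, rep(expected, 6), tolerance = 1e-12)
  expect_equal(sim$truth$delta_nox_true, rep(expected, 6), tolerance = 1e-12)

  # soil-only scenario: every month sits on the soil end-member
  soil_only <- synthetic_scenario(
    months = 3, nonsoil_rates = c(mobile = 0), soil_rates = 2,
    inventory_soil_rate = 0, signatures = toy_signatures(), noise_sd = 0,
    fractionation = fractionation_spec("parametric", f = 1, epsilon_eff = 0)
  )
  expect_equal(simulate_campaign(soil_only)$truth$delta_nox_true, rep(-33.2, 3))
})

test_that("fractionation and noise enter the forward model as configured", {
  sc <- synthetic_scenario(
    months = 4, nonsoil_rates = c(mobile = 10, stationary = 4),
    soil_rates = 5, signatures = toy_signatures(), noise_sd = 0,
    fractionation = fractionation_spec("parametric", f = 0.6, epsilon_eff = 5)
  )
  sim <- simulate_campaign(sc)
  # delta_NO2 = delta_NOx + (1 - f) * eps; correcting back recovers NOx
  expect_equal(sim$samples$delta_no2 - sim$truth$delta_nox_true, rep(2, 4))
  expect_equal(correct_no2_to_nox(sim$samples$delta_no2, sc$fractionation),
               sim$truth$delta_nox_true, tolerance = 1e-12)

  noisy <- synthetic_scenario(
    months = 200, nonsoil_rates = c(mobile = 10, stationary = 4),
    soil_rates = 5, signatures = toy_signatures(), noise_sd = 0.11, seed = 5
  )
  resid <- simulate_campaign(noisy)$samples$delta_no2 -
    simulate_campaign(noisy)$truth$delta_no2_true
  expect_equal(mean(resid), 0, tolerance = 0.03)
  expect_equal(stats::sd(resid), 0.11, tolerance = 0.03)
})

test_that("campaigns are byte-identical under a fixed seed and vary across reps", {
  sc <- synthetic_scenario(months = 8, signatures = default_signatures(),
                           signature_draw = "monthly_redraw", seed = 99)
  a <- simulate_campaign(sc)
  b <- simulate_campaign(sc)
  expect_identical(a, b)
  c <- simulate_campaign(sc, rep = 1)
  expect_false(identical(a$samples$delta_no2, c$samples$delta_no2))
})

test_that("hidden-truth deltas stay within the drawn source deltas", {
  sc <- synthetic_scenario(months = 24, signature_draw = "monthly_redraw",
                           seed = 13)
  truth <- simulate_campaign(sc)$truth
  src_cols <- c("delta_soil_used", "mobile", "biomass_burning", "stationary")
  lo <- apply(truth[src_cols], 1, min)
  hi <- apply(truth[src_cols], 1, max)
  expect_true(all(truth$delta_nox_true >= lo - 1e-12))
  expect_true(all(truth$delta_nox_true <= hi + 1e-12))
})

test_that("irrigation pulses multiply the soil profile in the chosen months", {
  base <- synthetic_scenario(months = 6, soil_rates = 2, noise_sd = 0)
  pulsed <- synthetic_scenario(months = 6, soil_rates = 2, noise_sd = 0,
                               pulse_months = c(2, 5), pulse_factor = 50)
  expect_equal(pulsed$soil_rates, c(2, 100, 2, 2, 100, 2))
  expect_equal(base$soil_rates, rep(2, 6))
})

test_that("recovery experiment: consistent estimator is exact without noise", {
  res <- recovery_experiment(toy_scenario(), "consistent", n_reps = 5)
  expect_equal(res$bias, 0, tolerance = 1e-9)
  expect_equal(res$rmse, 0, tolerance = 1e-9)
})

test_that("recovery experiment: inventory-based estimator carries the offset", {
  sc <- toy_scenario()
  res <- recovery_experiment(sc, "printed_eq1", n_reps = 5)
  # offset identity holds exactly per rep, so bias and RMSE vanish against
  # the offset-corrected target
  expect_equal(res$bias, 0, tolerance = 1e-9)
  expect_equal(res$rmse, 0, tolerance = 1e-9)
})

test_that("recovery experiment validates its configuration", {
  expect_error(recovery_experiment(toy_scenario(), "bogus"))
  expect_isonox_error(recovery_experiment(toy_scenario(), "consistent",
                                          n_reps = 0),
                      "isonox_invalid_input")
})

test_that("nominal 95 percent intervals cover in the linear regime", {
  # monthly signature redraw with sub-permil SDs plus analytic noise: the
  # analytic sigma describes the actual generative randomness, so coverage
  # of +/- 1.96 sigma should sit near 0.95
  sc <- synthetic_scenario(
    months = 12,
    nonsoil_rates = c(mobile = 12.4, stationary = 1.7),
    soil_rates = 6.7, inventory_soil_rate = 0.9,
    signatures = signature_set(
      source_signature("mobile", -2.5, 0.8),
      source_signature("stationary", -16.5, 0.5),
      source_signature("biogenic_soil", -33.2, 1.0)
    ),
    signature_draw = "monthly_redraw", noise_sd = 0.11, seed = 2024
  )
  res <- recovery_experiment(sc, "consistent", n_reps = 1000)
  expect_gte(res$coverage, 0.92)
  expect_lte(res$coverage, 0.98)
})
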