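toy_inputs <- function(sigma_i = c(0, 0), sigma_s = 9.6, sigma_obs = 0,
                       e_inv = 15) {
  # toy Imperial-like case: non-soil (10, 4) at (-2.5, -16.5), soil 1 of 15
  uncertainty_inputs(
    delta_obs = mix_delta(c(10, 4, 5), c(-2.5, -16.5, -33.2)),
    alpha = c(mobile = 10, stationary = 4) / 15,
    delta = c(-2.5, -16.5), sigma = sigma_i,
    alpha_s = 1 / 15, delta_s = -33.2, sigma_s = sigma_s,
    e_inv = e_inv, sigma_obs = sigma_obs
  )
}

test_that("analytic sigma matches the closed-form soil-only case", {
  # all sigmas zero -> zero
  expect_equal(sigma_soil_source(toy_inputs(sigma_s = 0)), 0)
  # only sigma_s: |dEs/ddelta_s| * sigma_s with
  # dEs/ddelta_s = -(alpha_s E_inv + E_s) / (delta_s - delta_obs)
  inp <- toy_inputs()
  D <- -33.2 - inp$delta_obs
  es <- (inp$delta_obs - (-8.28)) * 15 / D
  expect_equal(es, 4, tolerance = 1e-9)
  d_ds <- -(1 / 15) * 15 / D - es / D
  expect_equal(d_ds, 0.25415, tolerance = 1e-4)
  expect_equal(sigma_soil_source(inp), abs(d_ds) * 9.6, tolerance = 1e-12)
  expect_equal(round(sigma_soil_source(inp), 2), 2.44)
})

test_that("analytic sigma ignores zero-share sources and scales in E_inv", {
  base <- toy_inputs(sigma_i = c(2.7, 1.7))
  with_zero <- uncertainty_inputs(
    delta_obs = base$delta_obs,
    alpha = c(base$alpha, extra = 0), delta = c(base$delta, 7),
    sigma = c(base$sigma, 50),
    alpha_s = base$alpha_s, delta_s = base$delta_s, sigma_s = base$sigma_s,
    e_inv = base$e_inv
  )
  expect_equal(sigma_soil_source(with_zero), sigma_soil_source(base))

  # linear scaling in E_inv (alpha held fixed)
  doubled <- toy_inputs(sigma_i = c(2.7, 1.7), e_inv = 30)
  expect_equal(sigma_soil_source(doubled), 2 * sigma_soil_source(base),
               tolerance = 1e-12)
})

test_that("first-order homogeneity: doubling all sigmas doubles sigma_Es", {
  s1 <- sigma_soil_source(toy_inputs(sigma_i = c(0.5, 0.3), sigma_s = 0.8,
                                     sigma_obs = 0.11))
  s2 <- sigma_soil_source(toy_inputs(sigma_i = c(1.0, 0.6), sigma_s = 1.6,
                                     sigma_obs = 0.22))
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
})

test_that("Monte-Carlo oracle agrees with the analytic form", {
  # all sigmas zero -> degenerate spread
  mc0 <- mc_sigma_soil_source(toy_inputs(sigma_s = 0), n_draws = 2000, seed = 4)
  expect_equal(mc0$sigma, 0)

  # near-linear regime (sigmas <= 1 permil): agreement within a few percent
  inp <- toy_inputs(sigma_i = c(0.8, 0.5), sigma_s = 1.0, sigma_obs = 0.11)
  ana <- sigma_soil_source(inp)
  mc <- mc_sigma_soil_source(inp, n_draws = 2e5, seed = 7)
  expect_lt(abs(mc$sigma - ana) / ana, 0.05)
  expect_false(mc$high_rejection)
  expect_equal(mc$n_rejected, 0)

  # at the full soil signature SD (9.6 permil) the denominator is visibly
  # nonlinear; MC exceeds the first-order value but stays the same order
  inp_wide <- toy_inputs()
  mc_wide <- mc_sigma_soil_source(inp_wide, n_draws = 1e5, seed = 8)
  ana_wide <- sigma_soil_source(inp_wide)
  expect_gt(mc_wide$sigma, ana_wide)
  expect_lt(mc_wide$sigma, 10 * ana_wide)
})

test_that("Monte-Carlo draws are reproducible and validated", {
  inp <- toy_inputs(sigma_i = c(0.5, 0.5), sigma_s = 0.5)
  a <- mc_sigma_soil_source(inp, n_draws = 5000, seed = 42)
  b <- mc_sigma_soil_source(inp, n_draws = 5000, seed = 42)
  expect_identical(a$sigma, b$sigma)
  expect_isonox_error(mc_sigma_soil_source(inp, n_draws = 10), "isonox_invalid_input")
  expect_isonox_error(
    uncertainty_inputs(-10, c(a = 0.5), -2, -1, 0.1, -33.2, 1, 15),
    "isonox_invalid_input")
  expect_isonox_error(
    uncertainty_inputs(-10, c(a = 1.5), -2, 1, 0.1, -33.2, 1, 15),
    "isonox_invalid_input")
})
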