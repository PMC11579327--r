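test_that("mixing-model inversion matches hand-computed and published values", {
  # annual-mean inversion for the Imperial campaign
  expect_equal(round(soil_source_strength(-13.67, -5.04, 15.2, -33.2), 1), 6.7)
  # numerator vanishes when observed equals the a priori
  expect_equal(soil_source_strength(-5.04, -5.04, 15.2, -33.2), 0)
  # forward-mix fluxes (10, 4, 5) then invert with inventory soil 1.0:
  # recovers true soil 5 minus alpha_s * E_inv = 1
  d_obs <- mix_delta(c(10, 4, 5), c(-2.5, -16.5, -33.2))
  expect_equal(soil_source_strength(d_obs, -8.28, 15, -33.2), 4.0,
               tolerance = 1e-9)
})

test_that("inversion errors on invalid or singular inputs", {
  expect_isonox_error(soil_source_strength(-10, -5, 0, -33.2),
                      "isonox_invalid_input")
  expect_isonox_error(soil_source_strength(-33.2, -5, 15, -33.2),
                      "isonox_singularity")
  # configurable guard band around the soil end-member
  expect_isonox_error(soil_source_strength(-32.9, -5, 15, -33.2),
                      "isonox_singularity")
  expect_silent(soil_source_strength(-32.9, -5, 15, -33.2, guard_band = 0.1))
  expect_isonox_error(soil_source_strength(-30, -5, 15, -33.2, guard_band = 4),
                      "isonox_singularity")
})

test_that("consistent inversion solves the exact mass balance", {
  d_obs <- mix_delta(c(10, 4, 5), c(-2.5, -16.5, -33.2))
  expect_equal(consistent_soil_inversion(d_obs, c(10, 4), c(-2.5, -16.5), -33.2),
               5.0, tolerance = 1e-9)
  # observed equal to the non-soil mixture mean -> zero soil
  mix_ns <- mix_delta(c(10, 4), c(-2.5, -16.5))
  expect_equal(consistent_soil_inversion(mix_ns, c(10, 4), c(-2.5, -16.5), -33.2),
               0, tolerance = 1e-12)
  # observed heavier than any non-soil mixture -> no non-negative solution
  expect_isonox_error(
    consistent_soil_inversion(-3, c(10, 4), c(-2.5, -16.5), -33.2),
    "isonox_domain_error")
})

test_that("consistent inversion round-trips random forward mixtures", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(1:4, 1)
    rates <- runif(n, 0.5, 30)
    deltas <- runif(n, -20, 10)
    soil <- runif(1, 0.01, 40)
    d_obs <- mix_delta(c(rates, soil), c(deltas, -33.2))
    expect_equal(consistent_soil_inversion(d_obs, rates, deltas, -33.2), soil,
                 tolerance = 1e-9)
  }
})

test_that("offset identity: inventory-based inversion returns E_true - alpha_s * E_inv", {
  set.seed(12)
  nonsoil <- c(mobile = 10, stationary = 4)
  mu <- c(-2.5, -16.5)
  for (i in 1:100) {
    e_true <- runif(1, 0.5, 60)
    inv_soil <- runif(1, 0, 5)
    e_inv <- sum(nonsoil) + inv_soil
    apriori <- (sum(nonsoil * mu) + inv_soil * -33.2) / e_inv
    d_obs <- mix_delta(c(nonsoil, e_true), c(mu, -33.2))
    est <- soil_source_strength(d_obs, apriori, e_inv, -33.2)
    expect_equal(est, e_true - inv_soil, tolerance = 1e-9)
    expect_equal(consistent_soil_inversion(d_obs, nonsoil, mu, -33.2), e_true,
                 tolerance = 1e-9)
  }
})

test_that("inversion is strictly decreasing in delta_obs when soil is lightest", {
  grid <- seq(-25, 5, by = 0.5)
  es <- soil_source_strength(grid, -5.04, 15.2, -33.2)
  expect_true(all(diff(es) < 0))
})

test_that("series apportionment applies truncation and aggregates per policy", {
  thermal <- c(-16.1, -8.0, -8.0, -12.0, 0.2, -9.1, -3.2, -12.0, -7.6)
  res <- apportion_series(thermal, apriori = -3.11, e_inv = 18.0,
                          delta_soil = -33.2,
                          policy = apportionment_policy("mean_of_monthly"))
  expect_equal(round(res$periods$e_soil, 1),
               c(13.7, 3.5, 3.5, 7.5, 0, 4.5, 0.1, 7.5, 3.2))
  # November (delta_obs = 0.2) inverts negative and is truncated to zero
  nov <- res$periods[res$periods$delta_obs == 0.2, ]
  expect_equal(round(nov$e_soil_raw, 1), -1.8)
  expect_equal(nov$e_soil, 0)
  expect_true(nov$truncated)
  expect_equal(round(res$aggregate$e_soil, 1), 4.8)

  # truncated aggregate mean >= untruncated aggregate mean
  no_trunc <- apportion_series(thermal, -3.11, 18.0, -33.2,
                               apportionment_policy("mean_of_monthly",
                                                    truncate_negative = FALSE))
  expect_gte(res$aggregate$e_soil, no_trunc$aggregate$e_soil)
  expect_equal(no_trunc$periods$e_soil, no_trunc$periods$e_soil_raw)

  # constant series at the a priori -> all zeros
  res0 <- apportion_series(rep(-3.11, 4), -3.11, 18.0, -33.2)
  expect_equal(res0$periods$e_soil, rep(0, 4))
  expect_equal(res0$aggregate$e_soil, 0)

  # invert_mean_delta aggregates the delta series first
  res_m <- apportion_series(thermal, -3.11, 18.0, -33.2,
                            apportionment_policy("invert_mean_delta"))
  expect_equal(res_m$aggregate$e_soil,
               soil_source_strength(mean(thermal), -3.11, 18.0, -33.2))

  expect_isonox_error(apportion_series(c(NA_real_, NA_real_), -3.11, 18, -33.2),
                      "isonox_invalid_input")
})

test_that("policy overrides and missing values are honoured", {
  # override replaces the supplied a priori
  res <- apportion_series(c(-13.67), apriori = -99,
                          e_inv = 15.2, delta_soil = -33.2,
                          policy = apportionment_policy("invert_mean_delta",
                                                        apriori_override = -5.04))
  expect_equal(round(res$aggregate$e_soil, 1), 6.7)
  # missing observations are dropped, divisor reduced
  res2 <- apportion_series(c(-13.67, NA, NA), -5.04, 15.2, -33.2,
                           policy = apportionment_policy("mean_of_monthly"))
  expect_equal(nrow(res2$periods), 1)
  expect_equal(round(res2$aggregate$e_soil, 1), 6.7)
})
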