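test_that("emission rates convert to per-area N fluxes on the short-ton basis", {
  ctx <- conversion_context()
  expect_equal(round(tons_per_day_to_kgN_per_ha_yr(6.7, ctx), 1), 2.5)
  expect_equal(tons_per_day_to_kgN_per_ha_yr(0, ctx), 0)
  # inventoried soil rate 0.9 tons/d prints as 0.3 kg N/ha/yr
  expect_equal(report_round(tons_per_day_to_kgN_per_ha_yr(0.9, ctx)), 0.34)
  expect_equal(round(tons_per_day_to_kgN_per_ha_yr(0.9, ctx), 1), 0.3)
})

test_that("per-area conversion is linear and exactly invertible", {
  ctx <- conversion_context()
  r <- c(0, 0.9, 6.7, 11.4, 140)
  f <- tons_per_day_to_kgN_per_ha_yr(r, ctx)
  expect_equal(tons_per_day_to_kgN_per_ha_yr(3 * r, ctx), 3 * f)
  expect_equal(kgN_per_ha_yr_to_tons_per_day(f, ctx), r, tolerance = 1e-12)
})

test_that("fertilizer fraction reproduces the published percentage", {
  ctx <- conversion_context()
  expect_equal(round(fertilizer_fraction(6.7, ctx), 1), 1.3)
  expect_equal(fertilizer_fraction(0, ctx), 0)
  # doubling applied N halves the fraction
  ctx2 <- conversion_context(fertilizer_n = 2 * 57630)
  expect_equal(fertilizer_fraction(6.7, ctx2), fertilizer_fraction(6.7, ctx) / 2)
})

test_that("conversion context rejects non-positive constants", {
  expect_isonox_error(conversion_context(cropland_area = 0), "isonox_invalid_input")
  expect_isonox_error(conversion_context(fertilizer_n = -1), "isonox_invalid_input")
  expect_isonox_error(tons_per_day_to_kgN_per_ha_yr(-1), "isonox_invalid_input")
})

test_that("inventory revision replaces soil, conserves the rest, renormalizes shares", {
  ssab <- cepam_inventory("ssab")
  # unrevised basin inventory: soil share 3.0 % of the printed total
  expect_equal(round(100 * inventory_fractions(ssab)[["biogenic_soil"]], 1), 3.0)

  rev <- revise_inventory(ssab, 11.4)
  expect_equal(rev$rates[["biogenic_soil"]], 11.4)
  for (src in c("mobile", "biomass_burning", "stationary")) {
    expect_equal(rev$rates[[src]], ssab$rates[[src]])
  }
  expect_equal(inventory_total(rev), 28.3 + 0.8 + 3.0 + 11.4)
  sh <- attr(rev, "shares_percent")
  expect_equal(sum(sh), 100, tolerance = 1e-9)
  expect_equal(round(sh[["biogenic_soil"]], 1), 26.2)

  # revising with the existing soil rate leaves rates unchanged
  same <- revise_inventory(ssab, 1.0)
  expect_equal(same$rates, ssab$rates)

  expect_isonox_error(revise_inventory(ssab, -2), "isonox_invalid_input")
  no_soil <- emission_inventory(c(mobile = 5))
  expect_isonox_error(revise_inventory(no_soil, 1), "isonox_invalid_input")
})

test_that("shares of random revised inventories always sum to 100", {
  set.seed(31)
  for (i in 1:50) {
    rates <- stats::setNames(runif(4, 0, 30),
                             c("mobile", "biomass_burning", "stationary",
                               "biogenic_soil"))
    rates[1] <- rates[1] + 0.5
    inv <- emission_inventory(rates)
    rev <- revise_inventory(inv, runif(1, 0, 20))
    expect_equal(sum(attr(rev, "shares_percent")), 100, tolerance = 1e-9)
  }
})

test_that("NO2-tNO3 correlation handles missing pairs and edge shapes", {
  # perfectly linear and anti-linear pairs
  expect_equal(pearson_no2_no3(delta_no2 = 1:5, delta_tno3 = 2 * (1:5) - 3)$r, 1)
  expect_equal(pearson_no2_no3(delta_no2 = 1:5, delta_tno3 = -(1:5))$r, -1)

  # packaged campaign: 18 complete pairs, moderate positive correlation
  res <- pearson_no2_no3(field_samples())
  expect_equal(res$n, 18)
  expect_equal(round(res$r, 2), 0.50)

  expect_isonox_error(pearson_no2_no3(delta_no2 = c(1, 2), delta_tno3 = c(1, 2)),
                      "isonox_invalid_input")
  expect_isonox_error(
    pearson_no2_no3(delta_no2 = c(1, 2, 3, 4), delta_tno3 = c(1, 2, NA, NA)),
    "isonox_invalid_input")
})
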