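# Shared toy objects used across test files. The three-source toy mirrors a
# small inventory (10/4 non-soil tons/d plus soil) whose mixture delta can
# be hand-checked: (10*-2.5 + 4*-16.5 + 5*-33.2)/19 = -13.52632 permil.

toy_signatures <- function(sd_mobile = 2.7, sd_stationary = 1.7, sd_soil = 9.6) {
  signature_set(
    source_signature("mobile", -2.5, sd_mobile),
    source_signature("stationary", -16.5, sd_stationary),
    source_signature("biogenic_soil", -33.2, sd_soil)
  )
}

toy_scenario <- function(...) {
  synthetic_scenario(
    months = 6L,
    nonsoil_rates = c(mobile = 10, stationary = 4),
    soil_rates = 5,
    inventory_soil_rate = 1,
    signatures = toy_signatures(),
    fractionation = fractionation_spec("parametric", f = 1, epsilon_eff = 0),
    noise_sd = 0,
    ...
  )
}

expect_isonox_error <- function(expr, class) {
  expect_error(expr, class = class)
}
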