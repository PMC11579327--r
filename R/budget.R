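#' Unit-conversion context for emission budgets
#'
#' Constants for converting inventory-basis emission rates (short tons of
#' NOx per day, NO2-equivalent mass) into agronomic nitrogen fluxes.
#' Defaults describe the Imperial Valley: 270,500 ha of agricultural land
#' (MODIS land-surface characterization) and 57,630 short tons of nitrogen
#' fertilizer, minerals and compost purchased in 2022.
#'
#' @param cropland_area Cropland area, ha.
#' @param days_per_year Days per year (365).
#' @param kg_per_short_ton kg per short ton (907.185).
#' @param n_mass_fraction N mass fraction of NO2-equivalent NOx
#'   (14.007 / 46.0055).
#' @param fertilizer_n Applied N, short tons N per year.
#' @return An object of class `conversion_context`.
#' @export
conversion_context <- function(cropland_area = 270500,
                               days_per_year = 365,
                               kg_per_short_ton = 907.185,
                               n_mass_fraction = 14.007 / 46.0055,
                               fertilizer_n = 57630) {
  vals <- c(cropland_area, days_per_year, kg_per_short_ton,
            n_mass_fraction, fertilizer_n)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_invalid("conversion_context: all fields must be positive and finite")
  }
  structure(list(cropland_area = cropland_area, days_per_year = days_per_year,
                 kg_per_short_ton = kg_per_short_ton,
                 n_mass_fraction = n_mass_fraction,
                 fertilizer_n = fertilizer_n),
            class = "conversion_context")
}

#' Convert an emission rate to a per-area nitrogen flux
#'
#' rate (short tons NO2-equiv / d) x 365 d/yr x 907.185 kg/short ton x
#' N mass fraction / cropland area (ha) -> kg N ha^-1 yr^-1.
#'
#' @param rate Emission rate, short tons NO2-equivalent per day (>= 0).
#' @param ctx A [conversion_context()].
#' @return kg N per hectare per year.
#' @export
tons_per_day_to_kgN_per_ha_yr <- function(rate, ctx = conversion_context()) {
  if (!inherits(ctx, "conversion_context")) {
    stop_invalid("tons_per_day_to_kgN_per_ha_yr: ctx must be a conversion_context")
  }
  if (any(rate < 0)) stop_invalid("tons_per_day_to_kgN_per_ha_yr: rate must be >= 0")
  rate * ctx$days_per_year * ctx$kg_per_short_ton * ctx$n_mass_fraction /
    ctx$cropland_area
}

#' Inverse of [tons_per_day_to_kgN_per_ha_yr()]
#'
#' @param flux kg N per hectare per year (>= 0).
#' @inheritParams tons_per_day_to_kgN_per_ha_yr
#' @return Short tons NO2-equivalent per day.
#' @export
kgN_per_ha_yr_to_tons_per_day <- function(flux, ctx = conversion_context()) {
  if (any(flux < 0)) stop_invalid("kgN_per_ha_yr_to_tons_per_day: flux must be >= 0")
  flux * ctx$cropland_area /
    (ctx$days_per_year * ctx$kg_per_short_ton * ctx$n_mass_fraction)
}

#' Emission rate as a percentage of applied fertilizer nitrogen
#'
#' 100 x rate x 365 x N mass fraction / fertilizer_n, with rate and
#' fertilizer_n both in short tons (NO2-equivalent NOx and N respectively),
#' so the short-ton mass unit cancels.
#'
#' @inheritParams tons_per_day_to_kgN_per_ha_yr
#' @return Percent of applied N emitted as NOx-N.
#' @export
fertilizer_fraction <- function(rate, ctx = conversion_context()) {
  if (!inherits(ctx, "conversion_context")) {
    stop_invalid("fertilizer_fraction: ctx must be a conversion_context")
  }
  if (ctx$fertilizer_n <= 0) stop_invalid("fertilizer_fraction: fertilizer_n must be positive")
  if (any(rate < 0)) stop_invalid("fertilizer_fraction: rate must be >= 0")
  100 * rate * ctx$days_per_year * ctx$n_mass_fraction / ctx$fertilizer_n
}

#' Revise an inventory's soil source
#'
#' Replaces the biogenic-soil rate with an apportioned estimate, keeps all
#' other rates fixed, and recomputes the total and percentage shares (which
#' then sum to 100 by construction). Any stored printed total is dropped:
#' the revised inventory is internally consistent.
#'
#' @param inventory An [emission_inventory()].
#' @param e_soil Revised soil emission, short tons per day (>= 0).
#' @param soil_source Name of the soil source; default `"biogenic_soil"`.
#' @return An [emission_inventory()] with a `shares_percent` attribute.
#' @export
revise_inventory <- function(inventory, e_soil, soil_source = "biogenic_soil") {
  if (!inherits(inventory, "emission_inventory")) {
    stop_invalid("revise_inventory: not an emission_inventory")
  }
  if (!is.numeric(e_soil) || length(e_soil) != 1L || !is.finite(e_soil) || e_soil < 0) {
    stop_invalid("revise_inventory: e_soil must be a single non-negative number")
  }
  if (!soil_source %in% names(inventory$rates)) {
    stop_invalid(sprintf("revise_inventory: inventory has no '%s' source", soil_source))
  }
  rates <- inventory$rates
  rates[[soil_source]] <- e_soil
  out <- emission_inventory(rates, region = inventory$region, year = inventory$year)
  attr(out, "shares_percent") <- 100 * rates / sum(rates)
  out
}

#' Pearson correlation between paired NO2 and tNO3 delta series
#'
#' A descriptive check of whether the gas-phase and particulate nitrate
#' isotopes covary; pairs with a missing tNO3 value are dropped and at
#' least 3 complete pairs are required.
#'
#' @param samples Sample data frame with `delta_no2` and `delta_tno3`
#'   columns, or two numeric vectors via `delta_no2`/`delta_tno3`.
#' @param delta_no2,delta_tno3 Alternative vector interface.
#' @return A list: `r` (Pearson coefficient) and `n` (complete pairs).
#' @export
pearson_no2_no3 <- function(samples = NULL, delta_no2 = NULL, delta_tno3 = NULL) {
  if (!is.null(samples)) {
    if (!is.data.frame(samples) ||
        !all(c("delta_no2", "delta_tno3") %in% names(samples))) {
      stop_invalid("pearson_no2_no3: samples must contain delta_no2 and delta_tno3")
    }
    delta_no2 <- samples$delta_no2
    delta_tno3 <- samples$delta_tno3
  }
  keep <- is.finite(delta_no2) & is.finite(delta_tno3)
  n <- sum(keep)
  if (n < 3) stop_invalid("pearson_no2_no3: need at least 3 complete pairs")
  list(r = stats::cor(delta_no2[keep], delta_tno3[keep]), n = n)
}
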