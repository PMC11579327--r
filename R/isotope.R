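#' Isotope ratio pair
#'
#' Bundles a sample's 15N/14N ratio with the ratio of the reference standard
#' (atmospheric N2, whose isotopic composition is globally uniform). All
#' delta values in this package are per mil (parts per thousand) deviations
#' of the sample ratio from that standard.
#'
#' @param r_sample Dimensionless 15N/14N ratio of the sample. Must be > 0.
#' @param r_standard Dimensionless 15N/14N ratio of atmospheric N2. Must be > 0.
#' @return An object of class `isotope_ratio`.
#' @examples
#' delta_from_ratio(isotope_ratio(1.005, 1))
#' @export
isotope_ratio <- function(r_sample, r_standard) {
  if (!is.numeric(r_sample) || !is.numeric(r_standard) ||
      any(!is.finite(r_sample)) || any(!is.finite(r_standard)) ||
      any(r_sample <= 0) || any(r_standard <= 0)) {
    stop_invalid("isotope_ratio: r_sample and r_standard must be finite and strictly positive")
  }
  structure(list(r_sample = r_sample, r_standard = r_standard),
            class = "isotope_ratio")
}

#' Convert an isotope ratio to a delta value
#'
#' delta15N = (R_sample / R_standard - 1) x 10^3, in per mil.
#'
#' @param ratio An [isotope_ratio()].
#' @return delta15N in per mil.
#' @export
delta_from_ratio <- function(ratio) {
  if (!inherits(ratio, "isotope_ratio")) {
    ratio <- do.call(isotope_ratio, as.list(ratio))
  }
  (ratio$r_sample / ratio$r_standard - 1) * 1e3
}

#' Convert a delta value to a sample/standard ratio
#'
#' Algebraic inverse of the delta definition: returns
#' R_sample / R_standard = 1 + delta / 10^3.
#'
#' @param delta delta15N in per mil; must exceed -1000 (a ratio cannot be
#'   zero or negative).
#' @return Dimensionless ratio of sample to standard.
#' @export
ratio_from_delta <- function(delta) {
  if (!is.numeric(delta) || any(!is.finite(delta))) {
    stop_invalid("ratio_from_delta: delta must be finite")
  }
  if (any(delta <= -1000)) {
    stop_invalid("ratio_from_delta: delta must be > -1000 permil")
  }
  1 + delta / 1e3
}

#' Flux-weighted isotope mixing
#'
#' The linear mixing model underlying inventory-based source apportionment:
#' the delta15N of a mixture is the emission-flux-weighted mean of the
#' component deltas, sum(flux_i * delta_i) / sum(flux_i). The result is
#' always bounded by the component minimum and maximum.
#'
#' @param fluxes Non-negative emission rates (any common unit).
#' @param deltas delta15N of each component, per mil.
#' @return Mixture delta15N in per mil.
#' @export
mix_delta <- function(fluxes, deltas) {
  if (length(fluxes) != length(deltas)) {
    stop_invalid("mix_delta: fluxes and deltas must have equal length")
  }
  if (!is.numeric(fluxes) || !is.numeric(deltas) ||
      any(!is.finite(fluxes)) || any(!is.finite(deltas))) {
    stop_invalid("mix_delta: inputs must be finite numerics")
  }
  if (any(fluxes < 0)) stop_invalid("mix_delta: fluxes must be non-negative")
  total <- sum(fluxes)
  if (total <= 0) stop_invalid("mix_delta: total flux must be positive")
  sum(fluxes * deltas) / total
}
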