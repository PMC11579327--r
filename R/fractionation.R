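#' Fractionation correction specification
#'
#' Atmospheric processing fractionates nitrogen isotopes between NO and NO2,
#' so the delta15N of sampled NO2 is not in general the delta15N of emitted
#' NOx. Two correction modes are supported:
#'
#' * `table`: a per-sample additive correction Delta = delta15N-NOx -
#'   delta15N-NO2, typically recovered from a published table that reports
#'   both columns (see [implied_corrections()]). This is the authoritative
#'   mode for reproducing published campaigns.
#' * `parametric`: the standard single-factor form used in the
#'   delta15N-NO2 literature, delta15N-NOx = delta15N-NO2 - (1 - f) *
#'   epsilon_eff, where f is the NO2/NOx mixing-ratio fraction in (0, 1]
#'   and epsilon_eff (per mil) the effective NO<->NO2 equilibrium exchange
#'   fractionation. epsilon_eff may be supplied directly or generated from
#'   temperature by a user-supplied parameterization function; the constants
#'   are configuration, not code, and this mode is a documented
#'   approximation rather than a reproduction path.
#'
#' @param mode `"table"` or `"parametric"`.
#' @param delta Numeric vector of per-sample corrections, per mil
#'   (table mode).
#' @param f NO2/NOx mixing-ratio fraction in (0, 1] (parametric mode).
#' @param epsilon_eff Effective fractionation, per mil (parametric mode).
#' @param epsilon_fun Optional function(temperature_K) -> epsilon_eff used
#'   when `epsilon_eff` is missing; evaluated at `temperature_K`.
#' @param temperature_K Temperature passed to `epsilon_fun`.
#' @return An object of class `fractionation_spec`.
#' @export
fractionation_spec <- function(mode = c("table", "parametric"),
                               delta = NULL, f = NULL, epsilon_eff = NULL,
                               epsilon_fun = NULL, temperature_K = NULL) {
  mode <- match.arg(mode)
  if (mode == "table") {
    if (is.null(delta) || !is.numeric(delta) || any(!is.finite(delta))) {
      stop_config("fractionation_spec: table mode requires finite per-sample delta corrections")
    }
    return(structure(list(mode = "table", delta = as.numeric(delta)),
                     class = "fractionation_spec"))
  }
  if (is.null(f) || !is.numeric(f) || length(f) != 1L || !is.finite(f) ||
      f <= 0 || f > 1) {
    stop_invalid("fractionation_spec: f must be a single value in (0, 1]")
  }
  if (is.null(epsilon_eff)) {
    if (is.null(epsilon_fun)) {
      stop_config("fractionation_spec: parametric mode requires epsilon_eff or epsilon_fun")
    }
    if (is.null(temperature_K)) {
      stop_config("fractionation_spec: epsilon_fun requires temperature_K")
    }
    epsilon_eff <- epsilon_fun(temperature_K)
  }
  if (!is.numeric(epsilon_eff) || length(epsilon_eff) != 1L || !is.finite(epsilon_eff)) {
    stop_invalid("fractionation_spec: epsilon_eff must be a single finite value")
  }
  structure(list(mode = "parametric", f = f, epsilon_eff = as.numeric(epsilon_eff)),
            class = "fractionation_spec")
}

#' Correct observed delta15N-NO2 to emitted delta15N-NOx
#'
#' Table mode adds the per-sample correction Delta; parametric mode applies
#' delta15N-NOx = delta15N-NO2 - (1 - f) * epsilon_eff. With positive
#' epsilon_eff the parametric correction is non-positive: emitted NOx is
#' isotopically lighter than (or equal to) the sampled NO2.
#'
#' @param delta_no2 Observed delta15N-NO2, per mil (vector).
#' @param spec A [fractionation_spec()]. In table mode `spec$delta` must be
#'   length 1 or the length of `delta_no2`.
#' @return delta15N-NOx, per mil.
#' @export
correct_no2_to_nox <- function(delta_no2, spec) {
  if (!inherits(spec, "fractionation_spec")) {
    stop_config("correct_no2_to_nox: spec must be a fractionation_spec (no default correction exists)")
  }
  if (!is.numeric(delta_no2)) stop_invalid("correct_no2_to_nox: delta_no2 must be numeric")
  if (spec$mode == "table") {
    d <- spec$delta
    if (length(d) != 1L && length(d) != length(delta_no2)) {
      stop_invalid("correct_no2_to_nox: table corrections must be length 1 or match delta_no2")
    }
    return(delta_no2 + d)
  }
  delta_no2 - (1 - spec$f) * spec$epsilon_eff
}

#' Invert a fractionation correction (NOx -> NO2)
#'
#' Used by the campaign simulator to map a forward-modelled delta15N-NOx
#' back to the delta15N-NO2 a sampler would observe.
#'
#' @param delta_nox delta15N-NOx, per mil.
#' @inheritParams correct_no2_to_nox
#' @return delta15N-NO2, per mil.
#' @export
uncorrect_nox_to_no2 <- function(delta_nox, spec) {
  if (!inherits(spec, "fractionation_spec")) {
    stop_config("uncorrect_nox_to_no2: spec must be a fractionation_spec")
  }
  if (spec$mode == "table") {
    d <- spec$delta
    if (length(d) != 1L && length(d) != length(delta_nox)) {
      stop_invalid("uncorrect_nox_to_no2: table corrections must be length 1 or match delta_nox")
    }
    return(delta_nox - d)
  }
  delta_nox + (1 - spec$f) * spec$epsilon_eff
}

#' Per-sample corrections implied by paired NO2/NOx columns
#'
#' Recovers the additive correction Delta_i = delta15N-NOx_i -
#' delta15N-NO2_i from a sample table that reports both columns, for use in
#' table-mode correction of further samples.
#'
#' @param samples A sample data frame with columns `delta_no2` and
#'   `delta_nox` (see [read_samples()]).
#' @return Numeric vector of corrections, per mil (NA where either column
#'   is missing).
#' @export
implied_corrections <- function(samples) {
  if (!is.data.frame(samples) ||
      !all(c("delta_no2", "delta_nox") %in% names(samples))) {
    stop_invalid("implied_corrections: samples must contain delta_no2 and delta_nox columns")
  }
  samples$delta_nox - samples$delta_no2
}
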