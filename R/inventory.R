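#' Emission inventory for a region
#'
#' Per-source NOx emission rates in short tons per day on an NO2-equivalent
#' mass basis (the US inventory convention). Some published inventory tables
#' print a rounded total that differs slightly from the component sum; the
#' printed total may be carried alongside the components via `total` and is
#' then used as the default denominator for source proportions, matching how
#' such tables print their percentage shares.
#'
#' @param rates Named numeric vector, source -> short tons NOx per day (>= 0).
#' @param region Region identifier.
#' @param year Inventory year.
#' @param total Optional printed inventory total (short tons per day). When
#'   omitted the component sum is used everywhere.
#' @return An object of class `emission_inventory`.
#' @export
emission_inventory <- function(rates, region = "region", year = NA_integer_,
                               total = NULL) {
  if (!is.numeric(rates) || length(rates) == 0L || is.null(names(rates)) ||
      any(!nzchar(names(rates)))) {
    stop_invalid("emission_inventory: rates must be a non-empty named numeric vector")
  }
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop_invalid("emission_inventory: rates must be finite and >= 0")
  }
  if (sum(rates) <= 0) {
    stop_invalid("emission_inventory: at least one source must have a positive rate")
  }
  if (anyDuplicated(names(rates))) {
    stop_invalid("emission_inventory: duplicate source names")
  }
  if (!is.null(total)) {
    if (!is.numeric(total) || length(total) != 1L || !is.finite(total) || total <= 0) {
      stop_invalid("emission_inventory: total must be a single positive number")
    }
  }
  structure(
    list(region = region, year = as.integer(year),
         rates = stats::setNames(as.numeric(rates), names(rates)),
         total = if (is.null(total)) NULL else as.numeric(total)),
    class = "emission_inventory"
  )
}

#' Total inventory emission rate
#'
#' @param inventory An [emission_inventory()].
#' @param denominator `"printed"` (use the stored printed total when present,
#'   falling back to the component sum) or `"sum"` (always the component sum).
#' @return Short tons NOx per day.
#' @export
inventory_total <- function(inventory, denominator = c("printed", "sum")) {
  denominator <- match.arg(denominator)
  if (denominator == "printed" && !is.null(inventory$total)) {
    return(inventory$total)
  }
  sum(inventory$rates)
}

#' Per-source inventory proportions
#'
#' The proportion each source contributes to the overall inventory,
#' alpha_i = rate_i / total. With `denominator = "printed"` and a stored
#' printed total that differs from the component sum, the proportions sum to
#' sum(rates)/total rather than exactly 1 (a property of the printed table,
#' preserved deliberately).
#'
#' @inheritParams inventory_total
#' @return Named numeric vector of proportions in `[0, 1]`.
#' @export
inventory_fractions <- function(inventory, denominator = c("printed", "sum")) {
  if (!inherits(inventory, "emission_inventory")) {
    stop_invalid("inventory_fractions: not an emission_inventory")
  }
  total <- inventory_total(inventory, denominator)
  inventory$rates / total
}

#' A priori inventory delta15N-NOx signature
#'
#' The flux-weighted mean delta15N-NOx implied by an emission inventory's
#' source mix: mix_delta over inventory rates and signature means. Every
#' source with a nonzero rate must have a signature. When `override` is
#' supplied it is returned as authoritative (with a warning if it disagrees
#' with the computed value by more than `warn_tol`); this supports
#' reproducing published analyses whose printed a priori signature is not
#' recoverable from the printed tables.
#'
#' @param inventory An [emission_inventory()].
#' @param signatures A [signature_set()].
#' @param override Optional a priori signature in per mil, used as-is.
#' @param warn_tol Disagreement (per mil) above which a warning is emitted
#'   when `override` is supplied. Default 0.1.
#' @return A priori delta15N-NOx in per mil.
#' @export
apriori_signature <- function(inventory, signatures, override = NULL,
                              warn_tol = 0.1) {
  if (!inherits(inventory, "emission_inventory")) {
    stop_invalid("apriori_signature: not an emission_inventory")
  }
  active <- names(inventory$rates)[inventory$rates > 0]
  means <- signature_means(signatures, active)
  computed <- mix_delta(inventory$rates[active], means)
  if (is.null(override)) return(computed)
  if (!is.numeric(override) || length(override) != 1L || !is.finite(override)) {
    stop_invalid("apriori_signature: override must be a single finite number")
  }
  if (abs(override - computed) > warn_tol) {
    warning(sprintf(
      "a priori override %.2f permil differs from inventory-computed %.2f permil by %.2f permil",
      override, computed, abs(override - computed)), call. = FALSE)
  }
  override
}

#' @export
print.emission_inventory <- function(x, ...) {
  cat(sprintf("NOx emission inventory: %s (%s)\n", x$region,
              ifelse(is.na(x$year), "year unknown", x$year)))
  shares <- 100 * inventory_fractions(x)
  df <- data.frame(source = names(x$rates), rate_tons_per_day = x$rates,
                   share_percent = round(shares, 1), row.names = NULL)
  print(df, ...)
  cat(sprintf("total: %.1f tons/d%s\n", inventory_total(x),
              if (!is.null(x$total)) " (printed)" else ""))
  invisible(x)
}
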