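#' Source isotopic signature
#'
#' A NOx emission source class together with the literature mean and
#' standard deviation of its delta15N-NOx, optionally the reported range
#' and a provenance note. The canonical source classes are `mobile`,
#' `biomass_burning`, `stationary` and `biogenic_soil`; user-defined
#' classes are accepted.
#'
#' @param source Source class identifier.
#' @param mean_delta Mean delta15N-NOx, per mil.
#' @param sd_delta Standard deviation, per mil (>= 0).
#' @param range_low,range_high Optional reported range, per mil.
#' @param provenance Optional free-text provenance.
#' @return An object of class `source_signature`.
#' @export
source_signature <- function(source, mean_delta, sd_delta,
                             range_low = NA_real_, range_high = NA_real_,
                             provenance = NA_character_) {
  if (!is.character(source) || length(source) != 1L || !nzchar(source)) {
    stop_invalid("source_signature: source must be a non-empty string")
  }
  if (!is.finite(mean_delta)) stop_invalid("source_signature: mean_delta must be finite")
  if (!is.finite(sd_delta) || sd_delta < 0) {
    stop_invalid("source_signature: sd_delta must be finite and >= 0")
  }
  if (is.finite(range_low) && is.finite(range_high)) {
    if (range_low > range_high || mean_delta < range_low || mean_delta > range_high) {
      stop_invalid(sprintf(
        "source_signature(%s): mean_delta must lie within [range_low, range_high]", source))
    }
  }
  structure(
    list(source = source, mean_delta = as.numeric(mean_delta),
         sd_delta = as.numeric(sd_delta),
         range_low = as.numeric(range_low), range_high = as.numeric(range_high),
         provenance = provenance),
    class = "source_signature"
  )
}

#' Build a signature set from individual signatures
#'
#' @param ... `source_signature` objects (or a single list of them).
#' @return A named list of signatures, class `signature_set`.
#' @export
signature_set <- function(...) {
  sigs <- list(...)
  if (length(sigs) == 1L && !inherits(sigs[[1L]], "source_signature")) {
    sigs <- sigs[[1L]]
  }
  ok <- vapply(sigs, inherits, logical(1), "source_signature")
  if (length(sigs) == 0L || !all(ok)) {
    stop_invalid("signature_set: all elements must be source_signature objects")
  }
  nm <- vapply(sigs, `[[`, character(1), "source")
  if (anyDuplicated(nm)) stop_invalid("signature_set: duplicate source names")
  names(sigs) <- nm
  structure(sigs, class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("delta15N-NOx source signature set (", length(x), " sources)\n", sep = "")
  df <- data.frame(
    source = names(x),
    mean_delta = vapply(x, `[[`, numeric(1), "mean_delta"),
    sd_delta = vapply(x, `[[`, numeric(1), "sd_delta"),
    row.names = NULL
  )
  print(df, ...)
  invisible(x)
}

signature_means <- function(signatures, sources) {
  miss <- setdiff(sources, names(signatures))
  if (length(miss) > 0) {
    stop_config(sprintf("no signature for source(s): %s", paste(miss, collapse = ", ")))
  }
  vapply(signatures[sources], `[[`, numeric(1), "mean_delta")
}

signature_sds <- function(signatures, sources) {
  miss <- setdiff(sources, names(signatures))
  if (length(miss) > 0) {
    stop_config(sprintf("no signature for source(s): %s", paste(miss, collapse = ", ")))
  }
  vapply(signatures[sources], `[[`, numeric(1), "sd_delta")
}
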