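#' Packaged field-campaign fixtures
#'
#' The package ships plain-text transcriptions of the printed campaign
#' tables: the monthly delta15N sample table for the two Salton Sea Air
#' Basin sites (Calipatria, Imperial Valley; Thermal, Coachella Valley),
#' the delta15N-NOx source-signature library, and the CEPAM/NEI emission
#' inventories for Imperial County, the Coachella Valley, the combined air
#' basin (`"ssab"`), and the 2020 NEI comparison (`"imperial_nei"`).
#'
#' @param file Fixture file name; `isonox_fixture()` with no argument lists
#'   the available files.
#' @return `isonox_fixture()`: a path (or vector of file names);
#'   `field_samples()`: the validated sample table;
#'   `default_signatures()`: a [signature_set()];
#'   `cepam_inventory()`: an [emission_inventory()].
#' @export
isonox_fixture <- function(file = NULL) {
  dir <- system.file("extdata", package = "isonox", mustWork = TRUE)
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) stop_invalid(sprintf("no packaged fixture '%s'", file))
  path
}

#' @rdname isonox_fixture
#' @export
field_samples <- function() {
  read_samples(isonox_fixture("ssab_field_samples.csv"))
}

#' @rdname isonox_fixture
#' @export
default_signatures <- function() {
  read_signatures(isonox_fixture("nox_signatures.json"))
}

#' @rdname isonox_fixture
#' @param region One of `"imperial"`, `"coachella"`, `"ssab"`,
#'   `"imperial_nei"`.
#' @export
cepam_inventory <- function(region = c("imperial", "coachella", "ssab",
                                       "imperial_nei")) {
  region <- match.arg(region)
  read_inventory(isonox_fixture("cepam_inventory.csv"), region = region)
}
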