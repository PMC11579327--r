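#' Read a sample table
#'
#' CSV dialect: comma-separated, UTF-8, mandatory header
#' `site,period_start,period_end,delta_no2,delta_tno3,delta_nox,analytic_sd`,
#' ISO-8601 dates, `.` decimal separator, empty cell = missing. Lines
#' beginning with `#` (provenance headers written by [write_samples()]) are
#' skipped. Row numbers are preserved in error messages.
#'
#' @param path Path to the CSV file.
#' @return A data frame of validated samples (dates as `Date`).
#' @export
read_samples <- function(path) {
  df <- read_table_file(path, c("site", "period_start", "period_end",
                                "delta_no2", "delta_tno3", "delta_nox",
                                "analytic_sd"))
  for (col in c("delta_no2", "delta_tno3", "delta_nox", "analytic_sd")) {
    df[[col]] <- parse_numeric_column(df, col, path)
  }
  df$period_start <- parse_date_column(df, "period_start", path)
  df$period_end <- parse_date_column(df, "period_end", path)

  bad <- which(!is.na(df$period_start) & !is.na(df$period_end) &
                 df$period_end < df$period_start)
  if (length(bad) > 0) {
    stop_parse(sprintf("%s: row %d: period_end before period_start", path, bad[1]))
  }
  bad <- which(is.finite(df$analytic_sd) & df$analytic_sd < 0)
  if (length(bad) > 0) {
    stop_parse(sprintf("%s: row %d: analytic_sd must be >= 0", path, bad[1]))
  }
  key <- paste(df$site, df$period_start)
  if (anyDuplicated(key)) {
    stop_invalid(sprintf("%s: duplicate (site, period): %s", path,
                         key[duplicated(key)][1]))
  }
  df
}

#' Write a sample table
#'
#' @param samples Sample data frame.
#' @param path Output path.
#' @param provenance Optional named list appended to the provenance header
#'   comment (e.g. config hash, seed).
#' @export
write_samples <- function(samples, path, provenance = list()) {
  write_table_file(samples, path, provenance)
}

#' Read a source-signature library
#'
#' JSON array of objects with fields `source`, `mean_delta`, `sd_delta` and
#' optional `range_low`, `range_high`, `provenance`.
#'
#' @param path Path to the JSON file.
#' @return A [signature_set()].
#' @export
read_signatures <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("%s: file not found", path))
  recs <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
                   error = function(e) stop_parse(sprintf("%s: invalid JSON: %s",
                                                          path, conditionMessage(e))))
  if (length(recs) == 0) stop_parse(sprintf("%s: empty signature library", path))
  sigs <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    if (is.null(r$source) || is.null(r$mean_delta) || is.null(r$sd_delta)) {
      stop_parse(sprintf("%s: record %d: source, mean_delta and sd_delta are required",
                         path, i))
    }
    source_signature(r$source, r$mean_delta, r$sd_delta,
                     range_low = r$range_low %||% NA_real_,
                     range_high = r$range_high %||% NA_real_,
                     provenance = r$provenance %||% NA_character_)
  })
  signature_set(sigs)
}

#' Write a source-signature library
#'
#' @param signatures A [signature_set()].
#' @param path Output path (JSON).
#' @export
write_signatures <- function(signatures, path) {
  recs <- lapply(unname(unclass(signatures)), function(s) {
    s[vapply(s, function(x) length(x) == 1 && !is.na(x), logical(1))]
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an emission inventory
#'
#' CSV with header `region,year,source,rate_tons_per_day` and an optional
#' `printed_total` column carrying the table's printed inventory total
#' (used as the default denominator for source proportions when it differs
#' from the component sum).
#'
#' @param path Path to the CSV file.
#' @param region Region to extract; required when the file holds several.
#' @return An [emission_inventory()].
#' @export
read_inventory <- function(path, region = NULL) {
  df <- read_table_file(path, c("region", "year", "source", "rate_tons_per_day"))
  if (is.null(region)) {
    regions <- unique(df$region)
    if (length(regions) > 1) {
      stop_invalid(sprintf("%s: holds regions %s; specify one", path,
                           paste(regions, collapse = ", ")))
    }
    region <- regions
  }
  sub <- df[df$region == region, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop_invalid(sprintf("%s: no rows for region '%s'", path, region))
  }
  rates <- parse_numeric_column(sub, "rate_tons_per_day", path)
  if (anyDuplicated(sub$source)) {
    stop_invalid(sprintf("%s: duplicate source for region '%s'", path, region))
  }
  total <- NULL
  if ("printed_total" %in% names(sub)) {
    tt <- unique(parse_numeric_column(sub, "printed_total", path))
    tt <- tt[is.finite(tt)]
    if (length(tt) > 1) {
      stop_parse(sprintf("%s: conflicting printed_total values for region '%s'",
                         path, region))
    }
    if (length(tt) == 1) total <- tt
  }
  emission_inventory(stats::setNames(rates, sub$source), region = region,
                     year = unique(sub$year)[1], total = total)
}

#' Write an emission inventory
#'
#' @param inventory An [emission_inventory()].
#' @param path Output path.
#' @param provenance Optional provenance header entries.
#' @export
write_inventory <- function(inventory, path, provenance = list()) {
  df <- data.frame(region = inventory$region, year = inventory$year,
                   source = names(inventory$rates),
                   rate_tons_per_day = inventory$rates,
                   stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(inventory$total)) df$printed_total <- inventory$total
  write_table_file(df, path, provenance)
}

#' Read a run configuration
#'
#' YAML (or JSON) mapping with any of: `samples`, `signatures`, `inventory`,
#' `region`, `fractionation` (`mode`, plus `delta_table`/`f`/`epsilon_eff`),
#' `policy` (`aggregate_mode`, `truncate_negative`, `apriori_override`,
#' `guard_band`), `conversion` (fields of [conversion_context()]),
#' `delta_soil`, `out_dir`, `seed`, `log_level`. Relative paths are resolved
#' against the configuration file's directory.
#'
#' @param path Path to the YAML/JSON file.
#' @return A list of typed configuration pieces, class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("%s: file not found", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(cfg)) stop_parse(sprintf("%s: configuration must be a mapping", path))
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) return(p)
    file.path(base, p)
  }
  frac <- NULL
  if (!is.null(cfg$fractionation)) {
    fc <- cfg$fractionation
    frac <- if (identical(fc$mode, "table")) {
      tab <- read_samples(resolve(fc$delta_table))
      fractionation_spec("table", delta = implied_corrections(tab))
    } else {
      fractionation_spec("parametric", f = fc$f, epsilon_eff = fc$epsilon_eff)
    }
  }
  policy <- apportionment_policy(
    aggregate_mode = cfg$policy$aggregate_mode %||% "mean_of_monthly",
    truncate_negative = cfg$policy$truncate_negative %||% TRUE,
    apriori_override = cfg$policy$apriori_override,
    guard_band = cfg$policy$guard_band %||% 0.5
  )
  conv <- do.call(conversion_context, cfg$conversion %||% list())
  seed <- as.integer(cfg$seed %||% 1L)
  structure(list(
    samples_path = resolve(cfg$samples),
    signatures_path = resolve(cfg$signatures),
    inventory_path = resolve(cfg$inventory),
    region = cfg$region,
    fractionation = frac,
    policy = policy,
    conversion = conv,
    delta_soil = cfg$delta_soil %||% -33.2,
    out_dir = cfg$out_dir %||% ".",
    seed = seed,
    log_level = cfg$log_level %||% "info"
  ), class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_table_file <- function(path, required_cols) {
  if (!file.exists(path)) stop_parse(sprintf("%s: file not found", path))
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character", check.names = TRUE),
    error = function(e) stop_parse(sprintf("%s: %s", path, conditionMessage(e)))
  )
  if (nrow(df) == 0 && ncol(df) == 0) {
    stop_parse(sprintf("%s: empty file", path))
  }
  miss <- setdiff(required_cols, names(df))
  if (length(miss) > 0) {
    stop_parse(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")))
  }
  if (nrow(df) == 0) stop_parse(sprintf("%s: no data rows", path))
  df
}

parse_numeric_column <- function(df, col, path) {
  raw <- trimws(df[[col]])
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & nzchar(raw) & is.na(out))
  if (length(bad) > 0) {
    stop_parse(sprintf("%s: row %d, column %s: not a number ('%s')",
                       path, bad[1], col, raw[bad[1]]))
  }
  out
}

parse_date_column <- function(df, col, path) {
  raw <- trimws(df[[col]])
  out <- as.Date(rep(NA_character_, length(raw)))
  has <- !is.na(raw) & nzchar(raw)
  parsed <- suppressWarnings(as.Date(raw[has], format = "%Y-%m-%d"))
  if (anyNA(parsed)) {
    bad <- which(has)[which(is.na(parsed))[1]]
    stop_parse(sprintf("%s: row %d, column %s: not an ISO-8601 date ('%s')",
                       path, bad, col, raw[bad]))
  }
  out[has] <- parsed
  out
}

write_table_file <- function(df, path, provenance = list()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  header <- sprintf("# isonox %s; written %s",
                    as.character(utils::packageVersion("isonox")),
                    format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (length(provenance) > 0) {
    header <- paste0(header, "; ",
                     paste(names(provenance), unlist(provenance),
                           sep = "=", collapse = "; "))
  }
  writeLines(header, con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}
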