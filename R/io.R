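#' Read and write the long sub-daily record CSV dialect
#'
#' The canonical on-disk form is long CSV with columns `site_id`,
#' `timestamp` (ISO 8601 local standard time), `variable`, `value`,
#' `qc_flag`, `network`, `replicate_id`, `unit`. `read_records_csv()`
#' validates the header and parses timestamps; `write_records_csv()` writes
#' it back.
#'
#' @param path CSV file path.
#' @return A record tibble.
#' @export
read_records_csv <- function(path) {
  rec <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("site_id", "timestamp", "variable", "value")
  miss <- setdiff(required, names(rec))
  if (length(miss) > 0) {
    stop("records file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!inherits(rec$timestamp, "POSIXct")) {
    rec$timestamp <- as.POSIXct(rec$timestamp, tz = "UTC",
                                format = "%Y-%m-%dT%H:%M:%S")
  }
  attr(rec$timestamp, "tzone") <- "UTC"
  rec
}

#' @rdname read_records_csv
#' @param records record tibble.
#' @export
write_records_csv <- function(records, path) {
  out <- records
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S")
  readr::write_csv(out, path)
  invisible(path)
}

#' Read wide flux-tower CSV (FLUXNET-style column layout)
#'
#' Accepts one-row-per-timestamp files with one column per variable and
#' converts them to the long record dialect via a rename map from source
#' column names to canonical [SEB_VARIABLES] names (e.g.
#' `c(SW_IN_F = "SW_in", H_F = "H")`). Unmapped columns are ignored.
#'
#' @param path CSV path with a `TIMESTAMP` (or `timestamp`) column.
#' @param rename_map named character vector: source name -> canonical name.
#' @param site_id,network labels applied to all records.
#' @return A long record tibble.
#' @export
read_fluxnet_wide <- function(path, rename_map, site_id, network = "FLUXNET") {
  d <- readr::read_csv(path, show_col_types = FALSE)
  ts_col <- intersect(c("TIMESTAMP", "TIMESTAMP_START", "timestamp"),
                      names(d))[1]
  if (is.na(ts_col)) stop("no timestamp column found", call. = FALSE)
  ts <- d[[ts_col]]
  if (!inherits(ts, "POSIXct")) {
    ts <- if (is.numeric(ts) || all(grepl("^\\d{12}$", ts))) {
      as.POSIXct(as.character(ts), tz = "UTC", format = "%Y%m%d%H%M")
    } else {
      as.POSIXct(ts, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
    }
  }
  keep <- intersect(names(rename_map), names(d))
  purrr::map_dfr(keep, function(src) {
    tibble::tibble(site_id = site_id, timestamp = ts,
                   variable = unname(rename_map[[src]]),
                   value = as.numeric(d[[src]]),
                   qc_flag = "measured", network = network,
                   replicate_id = "r1",
                   unit = unit_of(unname(rename_map[[src]])))
  }) |>
    dplyr::arrange(.data$variable, .data$timestamp)
}

#' Write a wide daily table as CSV (one row per site-date)
#'
#' @param daily wide daily tibble.
#' @param path output path.
#' @export
write_daily_csv <- function(daily, path) {
  readr::write_csv(daily, path)
  invisible(path)
}
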