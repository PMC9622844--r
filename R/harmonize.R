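#' Quality-filter sub-daily SEB records
#'
#' Applies the basic record-level quality rules, in order:
#' \enumerate{
#'   \item drop records flagged `"gap-filled"` (only directly measured data
#'     are retained);
#'   \item drop shortwave/longwave radiation values > 1400 W m-2;
#'   \item drop negative incoming/outgoing radiation components;
#'   \item drop albedo values outside `[0, 1]`;
#'   \item drop air/surface temperatures < -100 degrees C.
#' }
#' Turbulent and ground heat fluxes may legitimately be negative and are not
#' sign-filtered. Removal counts per rule are attached as attribute
#' `"removal_log"` (see [removal_log()]).
#'
#' @param records tibble with at least `variable`, `value`, `qc_flag`.
#' @return Filtered records with a `removal_log` attribute.
#' @export
#' @examples
#' rec <- tibble::tibble(site_id = "A", variable = c("SW_in", "H"),
#'                       value = c(1500, -300), qc_flag = "measured")
#' removal_log(quality_filter(rec))
quality_filter <- function(records) {
  unknown <- setdiff(unique(records$variable), SEB_VARIABLES)
  if (length(unknown) > 0) {
    stop("unknown variable name(s): ", paste(unknown, collapse = ", "),
         "; accepted names are: ", paste(SEB_VARIABLES, collapse = ", "),
         call. = FALSE)
  }
  qc <- if ("qc_flag" %in% names(records)) records$qc_flag else "measured"
  is_rad <- records$variable %in% RADIATION_VARIABLES
  is_tmp <- records$variable %in% TEMPERATURE_VARIABLES
  is_alb <- records$variable == "albedo"

  drop_gapfill <- qc == "gap-filled"
  drop_rad_hi <- !drop_gapfill & is_rad & records$value > 1400
  drop_rad_neg <- !drop_gapfill & is_rad & records$value < 0
  drop_albedo <- !drop_gapfill & is_alb &
    (records$value < 0 | records$value > 1)
  drop_temp <- !drop_gapfill & is_tmp & records$value < -100
  drop <- drop_gapfill | drop_rad_hi | drop_rad_neg | drop_albedo | drop_temp
  drop[is.na(drop)] <- FALSE

  out <- records[!drop, ]
  attr(out, "removal_log") <- tibble::tibble(
    rule = c("gap_filled", "radiation_gt_1400", "radiation_negative",
             "albedo_outside_0_1", "temperature_lt_minus100"),
    n_removed = c(sum(drop_gapfill, na.rm = TRUE), sum(drop_rad_hi),
                  sum(drop_rad_neg), sum(drop_albedo), sum(drop_temp))
  )
  out
}

#' @rdname quality_filter
#' @param x an object returned by [quality_filter()].
#' @export
removal_log <- function(x) attr(x, "removal_log")

#' Harmonize the heat-flux sign convention
#'
#' The canonical direction convention is positive away from the surface for
#' the sensible, latent and ground heat fluxes (H, LE, G). Records declared
#' in the opposite convention are flipped exactly once; radiation components
#' are untouched.
#'
#' @param records sub-daily record tibble.
#' @param from the convention the records arrive in: `"away"` (no-op) or
#'   `"toward"` (H, LE, G negated).
#' @return Records in the positive-away convention.
#' @export
harmonize_flux_sign <- function(records, from = c("away", "toward")) {
  from <- match.arg(from)
  if (from == "toward") {
    flip <- records$variable %in% HEAT_FLUX_VARIABLES
    records$value[flip] <- -records$value[flip]
  }
  records
}

# Longest run of missing slots within the civil day; the day boundary closes
# runs. `slots` are 1-based present slot indices, `nominal` slots per day.
max_missing_run <- function(slots, nominal) {
  s <- sort.int(unique(slots))
  max(s[1] - 1L, nominal - s[length(s)], if (length(s) > 1) max(diff(s)) - 1L
      else 0L)
}

#' Aggregate sub-daily records to daily statistics
#'
#' Computes the daily (24 h) mean, minimum and maximum per site, date and
#' variable, retaining a day only when at least 65% of the nominal slots are
#' present and the longest internal run of missing slots is at most 4.8 h.
#' The completeness denominator is the full nominal day (48 half-hourly or
#' 24 hourly slots), and the day boundary closes missing runs. Replicated
#' sensors are averaged within each network first, then daily values are
#' averaged across networks.
#'
#' @param records quality-filtered record tibble (`site_id`, `timestamp`,
#'   `variable`, `value`, optionally `network`, `replicate_id`).
#' @param timestep_minutes nominal record spacing; all timestamps must fall
#'   on this grid (mixed timesteps within a site-day are an error).
#' @param min_completeness minimum present fraction of the nominal day.
#' @param max_gap_hours maximum tolerated contiguous gap.
#' @return Long daily tibble: `site_id`, `date`, `variable`, `mean`, `min`,
#'   `max`, `completeness`, `max_gap_hours`.
#' @export
aggregate_daily <- function(records, timestep_minutes = 60,
                            min_completeness = 0.65, max_gap_hours = 4.8) {
  if (!"network" %in% names(records)) records$network <- "net"
  if (!"replicate_id" %in% names(records)) records$replicate_id <- "r1"
  tod <- as.integer(format(records$timestamp, "%H")) * 60L +
    as.integer(format(records$timestamp, "%M"))
  if (any(tod %% timestep_minutes != 0)) {
    stop("records do not fall on a ", timestep_minutes,
         "-minute grid; mixed timesteps are not supported", call. = FALSE)
  }
  nominal <- as.integer(1440 / timestep_minutes)
  records$date <- as.Date(records$timestamp, tz = "UTC")
  records$slot <- tod %/% timestep_minutes + 1L

  per_stream <- records |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$site_id, .data$network, .data$replicate_id,
                    .data$date, .data$variable) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value), min = min(.data$value),
      max = max(.data$value),
      max_gap_slots = max_missing_run(.data$slot, .env$nominal),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      completeness = .data$n / nominal,
      max_gap_hours = .data$max_gap_slots * timestep_minutes / 60
    ) |>
    dplyr::filter(.data$completeness >= min_completeness,
                  .data$max_gap_hours <= .env$max_gap_hours)

  per_stream |>
    # replicate averaging within network (daily values)
    dplyr::group_by(.data$site_id, .data$network, .data$date,
                    .data$variable) |>
    dplyr::summarise(dplyr::across(c("mean", "min", "max", "completeness",
                                     "max_gap_hours"), mean),
                     .groups = "drop") |>
    # then cross-network averaging of daily values
    dplyr::group_by(.data$site_id, .data$date, .data$variable) |>
    dplyr::summarise(dplyr::across(c("mean", "min", "max", "completeness",
                                     "max_gap_hours"), mean),
                     .groups = "drop")
}

#' Pivot daily aggregates to one row per site-date
#'
#' @param daily long daily tibble from [aggregate_daily()].
#' @param stat which daily statistic to spread (default the mean).
#' @return Wide tibble: `site_id`, `date`, one column per variable.
#' @export
daily_wide <- function(daily, stat = "mean") {
  daily |>
    dplyr::select("site_id", "date", "variable", value = dplyr::all_of(stat)) |>
    tidyr::pivot_wider(names_from = "variable", values_from = "value")
}

#' Derive net radiation, net short-/longwave radiation and albedo
#'
#' Fills `SW_net = SW_in - SW_out`, `LW_net = LW_in - LW_out` and
#' `R_net = SW_net + LW_net` wherever the daily components exist. A
#' directly measured `R_net` column, where present, is preserved and only
#' missing entries are filled from the components. Daily albedo is the ratio
#' of daily mean reflected to incoming shortwave, defined only when
#' `SW_in >= sw_floor` (low-sun guard). The surface-air temperature
#' difference is added when both temperatures exist. Optionally, missing
#' surface temperature can be inverted from longwave-out through the
#' Stefan-Boltzmann law with emissivity 1 (off by default; surface
#' temperature is normally observed).
#'
#' @param daily wide daily table from [daily_wide()].
#' @param sw_floor minimum daily mean incoming shortwave (W m-2) for a valid
#'   albedo.
#' @param infer_tsurf if `TRUE`, fill missing `T_surf` from `LW_out`.
#' @return `daily` with derived columns added.
#' @export
derive_radiation <- function(daily, sw_floor = 10, infer_tsurf = FALSE) {
  has <- function(v) v %in% names(daily)
  col <- function(v) if (has(v)) daily[[v]] else rep(NA_real_, nrow(daily))
  sw_net <- col("SW_in") - col("SW_out")
  lw_net <- col("LW_in") - col("LW_out")
  daily$SW_net <- sw_net
  daily$LW_net <- lw_net
  derived_rnet <- sw_net + lw_net
  daily$R_net <- if (has("R_net")) {
    ifelse(is.na(daily$R_net), derived_rnet, daily$R_net)
  } else derived_rnet
  daily$albedo <- ifelse(!is.na(col("SW_in")) & col("SW_in") >= sw_floor,
                         col("SW_out") / col("SW_in"), NA_real_)
  if (has("T_surf") && has("T_air")) {
    daily$T_diff <- daily$T_surf - daily$T_air
  }
  if (infer_tsurf && has("LW_out")) {
    inferred <- (pmax(daily$LW_out, 0) / SIGMA_SB)^0.25 - 273.15
    daily$T_surf <- if (has("T_surf")) {
      ifelse(is.na(daily$T_surf), inferred, daily$T_surf)
    } else inferred
  }
  daily
}

#' Full daily harmonization of a sub-daily record stream
#'
#' Convenience wrapper: [quality_filter()], [harmonize_flux_sign()],
#' [aggregate_daily()], [daily_wide()], [derive_radiation()].
#'
#' @inheritParams aggregate_daily
#' @inheritParams harmonize_flux_sign
#' @inheritParams derive_radiation
#' @return Wide daily tibble of harmonized means with derived radiation.
#' @export
harmonize_daily <- function(records, timestep_minutes = 60, from = "away",
                            sw_floor = 10) {
  records |>
    quality_filter() |>
    harmonize_flux_sign(from = from) |>
    aggregate_daily(timestep_minutes = timestep_minutes) |>
    daily_wide() |>
    derive_radiation(sw_floor = sw_floor)
}
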