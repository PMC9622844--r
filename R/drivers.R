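#' Conrad continentality index
#'
#' `1.7 * (T_max - T_min) / sin(phi + 10 deg) - 14`, where `T_max` and
#' `T_min` are the mean air temperatures of the warmest and coldest month
#' and `phi` is latitude. Conrad's classical form evaluates the sine with
#' latitude in degrees (so the `+10` offset is a 10-degree shift); this is
#' the default, switchable with `degrees = FALSE` for a literal
#' radians-plus-10 reading, which is dimensionally implausible and kept
#' only for comparison.
#'
#' @param monthly_T numeric vector of 12 monthly mean temperatures (degrees
#'   C), or a matrix/data frame with 12 columns (one row per year; the index
#'   is averaged over years).
#' @param latitude_deg latitude in degrees.
#' @param degrees evaluate `sin(phi + 10)` in degrees (classical form).
#' @return The continentality index (dimensionless).
#' @export
#' @examples
#' conrad_continentality(rep(5, 12), 68)           # zero annual range: -14
#' conrad_continentality(c(-24.7, -20, -15, -5, 2, 10, 15.3,
#'                         12, 5, -5, -15, -22), 68)
conrad_continentality <- function(monthly_T, latitude_deg, degrees = TRUE) {
  if (is.matrix(monthly_T) || is.data.frame(monthly_T)) {
    m <- as.matrix(monthly_T)
    if (ncol(m) != 12) stop("need 12 monthly values per year", call. = FALSE)
    return(mean(apply(m, 1, conrad_continentality, latitude_deg = latitude_deg,
                      degrees = degrees)))
  }
  if (length(monthly_T) != 12) {
    stop("need 12 monthly mean temperatures", call. = FALSE)
  }
  rng <- max(monthly_T) - min(monthly_T)
  s <- if (degrees) sin((latitude_deg + 10) * pi / 180) else
    sin(latitude_deg * pi / 180 + 10)
  if (abs(s) < .Machine$double.eps) {
    stop("sin(latitude + 10) is zero; index undefined", call. = FALSE)
  }
  1.7 * rng / s - 14
}

#' Summer warmth index
#'
#' Annual sum of monthly mean air temperatures above 0 degrees C
#' (degree C-months). Multi-year input (matrix/data frame, one row per
#' year) is averaged across years.
#'
#' @inheritParams conrad_continentality
#' @return SWI in degree C-months (>= 0).
#' @export
#' @examples
#' summer_warmth_index(c(rep(-20, 4), 3, 8, 12, 10, 4, rep(-10, 3))) # 37
summer_warmth_index <- function(monthly_T) {
  if (is.matrix(monthly_T) || is.data.frame(monthly_T)) {
    m <- as.matrix(monthly_T)
    if (ncol(m) != 12) stop("need 12 monthly values per year", call. = FALSE)
    return(mean(apply(m, 1, summer_warmth_index)))
  }
  if (length(monthly_T) != 12) {
    stop("need 12 monthly mean temperatures", call. = FALSE)
  }
  sum(pmax(monthly_T, 0))
}

#' Annual snow amount (snow water equivalent proxy)
#'
#' Annual sum of daily precipitation falling on days with daily mean air
#' temperature at or below 0 degrees C (the threshold is inclusive).
#' With a `year` vector, yearly sums are averaged across years.
#'
#' @param daily_T daily mean air temperature (degrees C).
#' @param daily_precip daily precipitation (mm), same length.
#' @param year optional year label per day.
#' @return Mean annual snow amount (mm per year).
#' @export
snow_amount <- function(daily_T, daily_precip, year = NULL) {
  if (length(daily_T) != length(daily_precip)) {
    stop("`daily_T` and `daily_precip` must have the same length",
         call. = FALSE)
  }
  cold <- !is.na(daily_T) & daily_T <= 0
  contrib <- ifelse(cold, daily_precip, 0)
  if (is.null(year)) return(sum(contrib, na.rm = TRUE))
  mean(tapply(contrib, year, sum, na.rm = TRUE))
}

#' Snow phenology from a daily snow-category series
#'
#' Derives, per year, the spring snow-free date (mean of the days of year of
#' the last spring "snow" day and the first "no snow" day), the autumn
#' snow-onset date (mean of the last autumn "no snow" day and the first
#' autumn "snow" day) and their difference (snow-free duration). To be
#' robust to transient midsummer snow, the spring transition is searched in
#' DOY 1-212 taking the last snow-to-no-snow transition, and the autumn
#' transition in DOY 182-366 taking the first no-snow-to-snow transition.
#' Years without the respective transition are flagged missing.
#'
#' @param doy integer days of year of the observations (sorted).
#' @param snow character/factor series of "snow" / "no snow", same length.
#' @param spring_window,autumn_window inclusive DOY search windows.
#' @return A one-row tibble: `snow_free_doy`, `snow_onset_doy`, `duration`.
#' @export
#' @examples
#' doy <- 1:365
#' snow_phenology(doy, ifelse(doy >= 141 & doy < 280, "no snow", "snow"))
snow_phenology <- function(doy, snow, spring_window = c(1, 212),
                           autumn_window = c(182, 366)) {
  ok <- !is.na(snow)
  doy <- doy[ok]
  snow <- as.character(snow[ok])
  is_snow <- snow == "snow"
  trans <- which(is_snow[-length(is_snow)] != is_snow[-1])

  snow_free <- NA_real_
  spring <- trans[is_snow[trans] &
                    doy[trans] >= spring_window[1] &
                    doy[trans + 1] <= spring_window[2]]
  if (length(spring) > 0) {
    i <- spring[length(spring)] # last spring transition
    snow_free <- mean(c(doy[i], doy[i + 1]))
  }
  snow_onset <- NA_real_
  autumn <- trans[!is_snow[trans] &
                    doy[trans] >= autumn_window[1] &
                    doy[trans + 1] <= autumn_window[2]]
  if (length(autumn) > 0) {
    i <- autumn[1] # first autumn transition
    snow_onset <- mean(c(doy[i], doy[i + 1]))
  }
  tibble::tibble(snow_free_doy = snow_free, snow_onset_doy = snow_onset,
                 duration = snow_onset - snow_free)
}

#' Per-site-year snow phenology table
#'
#' @param snow daily snow series: `site_id`, `date`, `snow`.
#' @return Tibble `site_id`, `year`, `snow_free_doy`, `snow_onset_doy`,
#'   `duration`.
#' @export
snow_phenology_table <- function(snow) {
  snow |>
    dplyr::mutate(year = as.integer(format(.data$date, "%Y")),
                  doy = doy_noleap(.data$date)) |>
    dplyr::filter(!is.na(.data$doy)) |>
    dplyr::group_by(.data$site_id, .data$year) |>
    dplyr::arrange(.data$doy, .by_group = TRUE) |>
    dplyr::reframe(snow_phenology(.data$doy, .data$snow))
}

#' Assemble the 15-driver site table
#'
#' Combines the categorical drivers carried in the site metadata
#' (vegetation type, CAVM type and subzone, permafrost extent and ice
#' content) and the metadata-supplied numeric drivers (cloud cover and
#' cloud-top temperature, latitude, altitude) with drivers computed here
#' from the per-site climate and snow series: mean annual air temperature,
#' annual precipitation, summer warmth index, Conrad continentality, snow
#' amount and median annual snow-cover duration.
#'
#' @param metadata site table (see [generate_network()]).
#' @param climate daily climate series: `site_id`, `date`, `t_air`,
#'   `precip`.
#' @param snow daily snow-category series: `site_id`, `date`, `snow`.
#' @return Tibble with `site_id` and the 15 driver columns of
#'   [DRIVER_NAMES].
#' @export
build_driver_table <- function(metadata, climate, snow) {
  clim <- climate |>
    dplyr::mutate(year = as.integer(format(.data$date, "%Y")),
                  month = as.integer(format(.data$date, "%m")))
  monthly <- clim |>
    dplyr::group_by(.data$site_id, .data$year, .data$month) |>
    dplyr::summarise(t = mean(.data$t_air, na.rm = TRUE), .groups = "drop")

  clim_drivers <- clim |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      temperature = mean(.data$t_air, na.rm = TRUE),
      precipitation = sum(.data$precip, na.rm = TRUE) /
        dplyr::n_distinct(.data$year),
      snow_amount = snow_amount(.data$t_air, .data$precip, .data$year),
      .groups = "drop"
    )
  indices <- monthly |>
    tidyr::pivot_wider(names_from = "month", values_from = "t") |>
    dplyr::group_by(.data$site_id) |>
    dplyr::reframe(
      summer_warmth = summer_warmth_index(dplyr::pick(dplyr::matches("^\\d+$"))),
      continentality = {
        lat <- metadata$latitude[match(.data$site_id[1], metadata$site_id)]
        conrad_continentality(dplyr::pick(dplyr::matches("^\\d+$")), lat)
      }
    )
  snow_dur <- snow_phenology_table(snow) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(snow_duration = median(.data$duration, na.rm = TRUE))

  metadata |>
    dplyr::select("site_id", "vegetation_type", "cavm_type", "cavm_subzone",
                  "permafrost_extent", "permafrost_ice", "cloud_cover",
                  "cloud_temperature", "latitude", "altitude") |>
    dplyr::left_join(clim_drivers, by = "site_id") |>
    dplyr::left_join(indices, by = "site_id") |>
    dplyr::left_join(snow_dur, by = "site_id") |>
    dplyr::select("site_id", dplyr::all_of(DRIVER_NAMES))
}

# DOY on a 365-day axis: Feb 29 returns NA and later days shift back by one
doy_noleap <- function(date) {
  y <- as.integer(format(date, "%Y"))
  j <- as.integer(format(date, "%j"))
  leap <- (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0
  out <- j
  out[leap & j == 60] <- NA_integer_
  out[leap & j > 60] <- j[leap & j > 60] - 1L
  out
}
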