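#' Solar geometry helpers
#'
#' Standard solar position formulas (Spencer Fourier series for declination
#' and Sun-Earth distance). `solar_declination()` returns the declination in
#' radians, `eccentricity_factor()` the squared inverse relative Sun-Earth
#' distance, and `cos_zenith()` the cosine of the solar zenith angle at a
#' given latitude, day of year and local solar hour.
#'
#' @param doy day of year (1-366).
#' @param latitude_deg latitude in degrees north.
#' @param hour local solar time in hours (12 = solar noon).
#' @name solar-geometry
NULL

#' @rdname solar-geometry
#' @export
solar_declination <- function(doy) {
  g <- 2 * pi * (doy - 1) / 365
  0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
}

#' @rdname solar-geometry
#' @export
eccentricity_factor <- function(doy) {
  g <- 2 * pi * (doy - 1) / 365
  1.000110 + 0.034221 * cos(g) + 0.001280 * sin(g) +
    0.000719 * cos(2 * g) + 0.000077 * sin(2 * g)
}

#' @rdname solar-geometry
#' @export
cos_zenith <- function(latitude_deg, doy, hour) {
  phi <- latitude_deg * pi / 180
  dec <- solar_declination(doy)
  ha <- (hour - 12) * 15 * pi / 180
  sin(phi) * sin(dec) + cos(phi) * cos(dec) * cos(ha)
}

#' Daily maximum potential incoming shortwave radiation
#'
#' Top-of-atmosphere irradiance on a horizontal surface at the day's minimum
#' solar zenith angle (solar noon): `S0 * E0(doy) * cos(z_min)` with solar
#' constant `S0 = 1361` W m-2 and eccentricity factor `E0`. Zero on days the
#' sun never rises. Topographic shading and atmospheric transmission are
#' deliberately not modeled; the quantity only needs to provide a consistent
#' seasonal-latitudinal scale for flux normalization.
#'
#' @param latitude degrees north, in `[-90, 90]`.
#' @param longitude degrees east (unused by the horizontal-surface maximum;
#'   accepted for interface symmetry with site metadata).
#' @param date a `Date` vector (or day-of-year integers).
#' @return Potential shortwave maximum in W m-2 (vectorized).
#' @export
#' @examples
#' max_potential_sw(75, 0, as.Date("2010-12-21")) # polar night: 0
#' max_potential_sw(0, 0, as.Date("2010-03-21"))  # ~ S0 * E0
max_potential_sw <- function(latitude, longitude = NA_real_, date) {
  if (any(!is.finite(latitude)) || any(latitude < -90 | latitude > 90)) {
    stop("`latitude` must be in [-90, 90]", call. = FALSE)
  }
  doy <- if (inherits(date, "Date")) as.integer(format(date, "%j")) else
    as.integer(date)
  cz <- cos_zenith(latitude, doy, 12)
  SOLAR_CONSTANT * eccentricity_factor(doy) * pmax(cz, 0)
}

#' Potential-shortwave table for a set of sites and dates
#'
#' @param metadata site table with `site_id`, `latitude`, `longitude`.
#' @param dates `Date` vector.
#' @return Tibble `site_id`, `date`, `s_pot_max` (W m-2).
#' @export
potential_sw_table <- function(metadata, dates) {
  tidyr::expand_grid(site_id = metadata$site_id, date = dates) |>
    dplyr::left_join(metadata[, c("site_id", "latitude", "longitude")],
                     by = "site_id") |>
    dplyr::mutate(s_pot_max = max_potential_sw(.data$latitude,
                                               .data$longitude,
                                               .data$date)) |>
    dplyr::select("site_id", "date", "s_pot_max")
}

#' Normalize daily fluxes by potential shortwave
#'
#' Expresses daily fluxes as a percentage of the day's maximum potential
#' incoming shortwave radiation: `n.X = 100 * X / s_pot_max` for
#' X in {R_net, SW_net, LW_net, H, LE, G}. Normalized values are missing
#' when `s_pot_max` falls below `floor_w_m2` (polar night guard).
#'
#' @param daily wide daily table with a `site_id` and `date` column and flux
#'   columns (see [derive_radiation()]).
#' @param pot potential table from [potential_sw_table()]; computed from
#'   `metadata` if omitted.
#' @param metadata site table (needed when `pot` is missing).
#' @param floor_w_m2 minimum potential for a defined normalized flux.
#' @return `daily` with added `n.*` columns.
#' @export
normalize_fluxes <- function(daily, pot = NULL, metadata = NULL,
                             floor_w_m2 = 1) {
  if (is.null(pot)) {
    if (is.null(metadata)) {
      stop("supply either `pot` or `metadata`", call. = FALSE)
    }
    pot <- potential_sw_table(metadata, unique(daily$date))
  }
  out <- dplyr::left_join(daily, pot[, c("site_id", "date", "s_pot_max")],
                          by = c("site_id", "date"))
  for (v in c("R_net", "SW_net", "LW_net", "H", "LE", "G")) {
    if (v %in% names(out)) {
      out[[paste0("n.", v)]] <-
        ifelse(out$s_pot_max >= floor_w_m2,
               100 * out[[v]] / out$s_pot_max, NA_real_)
    }
  }
  out
}
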