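#' Day-of-year climatology per vegetation type
#'
#' Averages daily values per site and day of year across all available
#' years, then per vegetation type per DOY (mean and standard error across
#' sites). Feb 29 is dropped so every year maps to DOY 1-365. Following the
#' data-availability constraints of circumpolar archives, the default
#' window starts in 2000 and the barren class (which typically lacks net
#' radiation) is excluded.
#'
#' @param daily wide daily table.
#' @param metadata site table with `site_id`, `vegetation_type`.
#' @param variables columns of `daily` to build curves for.
#' @param year_min,year_max inclusive year window.
#' @param exclude_types vegetation classes to drop.
#' @return Tibble: `vegetation_type`, `variable`, `doy`, `mean`, `se`,
#'   `n_sites`, `n_site_years`.
#' @export
doy_climatology <- function(daily, metadata,
                            variables = intersect(
                              c("R_net", "SW_net", "LW_net", "H", "LE", "G",
                                "albedo", "T_surf", "T_air", "T_diff"),
                              names(daily)),
                            year_min = 2000, year_max = 2021,
                            exclude_types = "barren") {
  d <- daily |>
    dplyr::mutate(year = as.integer(format(.data$date, "%Y")),
                  doy = doy_noleap(.data$date)) |>
    dplyr::filter(!is.na(.data$doy), .data$year >= year_min,
                  .data$year <= year_max) |>
    dplyr::inner_join(metadata[, c("site_id", "vegetation_type")],
                      by = "site_id") |>
    dplyr::filter(!.data$vegetation_type %in% exclude_types)

  purrr::map_dfr(variables, function(v) {
    site_doy <- d |>
      dplyr::group_by(.data$vegetation_type, .data$site_id, .data$doy) |>
      dplyr::summarise(value = mean(.data[[v]], na.rm = TRUE),
                       n_years = sum(!is.na(.data[[v]])),
                       .groups = "drop") |>
      dplyr::filter(!is.nan(.data$value))
    site_doy |>
      dplyr::group_by(.data$vegetation_type, .data$doy) |>
      dplyr::summarise(
        variable = v,
        mean = mean(.data$value),
        se = if (dplyr::n() > 1) sd(.data$value) / sqrt(dplyr::n()) else 0,
        n_sites = dplyr::n(),
        n_site_years = sum(.data$n_years > 0),
        .groups = "drop"
      ) |>
      dplyr::select("vegetation_type", "variable", "doy", dplyr::everything())
  })
}

#' Centered 15-day circular moving average
#'
#' Smooths a DOY series with a centered 15-day window that wraps across the
#' year boundary (DOY 1 neighbors DOY 365). Missing values inside a window
#' are ignored; a smoothed value requires at least `min_present` of the 15
#' days. The filter is linear and mean-preserving on complete circular
#' series, and phase-preserving for a pure annual harmonic (the amplitude
#' shrinks by the Dirichlet factor `sin(15*pi/365) / (15*sin(pi/365))`).
#'
#' @param x numeric vector indexed by DOY 1..365 (length 365).
#' @param window odd window length in days.
#' @param min_present minimum non-missing days per window.
#' @return Smoothed vector, same length.
#' @export
smooth_15d <- function(x, window = 15, min_present = 8) {
  n <- length(x)
  half <- (window - 1) / 2
  idx <- outer(seq_len(n), -half:half, function(i, k) ((i + k - 1) %% n) + 1)
  vals <- matrix(x[idx], nrow = n)
  cnt <- rowSums(!is.na(vals))
  out <- rowMeans(vals, na.rm = TRUE)
  out[cnt < min_present] <- NA_real_
  out
}

#' @rdname smooth_15d
#' @param curve a climatology tibble from [doy_climatology()].
#' @return `smooth_curves()`: the tibble with `mean` and `se` smoothed per
#'   (vegetation type, variable), flagged `smoothed = TRUE`.
#' @export
smooth_curves <- function(curve, window = 15, min_present = 8) {
  curve |>
    dplyr::group_by(.data$vegetation_type, .data$variable) |>
    dplyr::arrange(.data$doy, .by_group = TRUE) |>
    dplyr::mutate(
      mean = smooth_15d(pad365(.data$mean, .data$doy), window,
                        min_present)[.data$doy],
      se = smooth_15d(pad365(.data$se, .data$doy), window,
                      min_present)[.data$doy],
      smoothed = TRUE
    ) |>
    dplyr::ungroup()
}

# place values on a full 1..365 axis (missing DOYs become NA)
pad365 <- function(x, doy) {
  out <- rep(NA_real_, 365)
  out[doy] <- x
  out
}

#' Detect the summer-regime period of a smoothed seasonal curve
#'
#' The summer regime is the longest contiguous run of days satisfying the
#' regime condition: values above 0 (W m-2 for fluxes, degrees C for
#' surface temperature), or, for albedo, values below the midpoint of the
#' smoothed curve's annual minimum and maximum. Latent heat flux is
#' excluded by policy (it stays positive essentially year-round). The
#' longest-run rule makes the detection robust to brief noise-driven sign
#' flips in the shoulder seasons; on smooth unimodal curves it coincides
#' with the first/last crossing.
#'
#' @param values smoothed daily values on a DOY 1..365 axis.
#' @param variable variable name; decides threshold and orientation.
#' @return One-row tibble: `start_doy`, `end_doy`, `threshold` (NA if no
#'   DOY satisfies the condition).
#' @export
#' @examples
#' x <- 100 * sin(2 * pi * ((1:365) - 81) / 365)
#' detect_summer_regime(smooth_15d(x), "R_net")
detect_summer_regime <- function(values, variable) {
  if (variable == "LE") {
    stop("latent heat flux is excluded from summer-regime detection",
         call. = FALSE)
  }
  if (variable == "albedo") {
    thr <- mean(range(values, na.rm = TRUE))
    cond <- values < thr
  } else {
    thr <- 0
    cond <- values > thr
  }
  cond[is.na(cond)] <- FALSE
  if (!any(cond)) {
    return(tibble::tibble(start_doy = NA_integer_, end_doy = NA_integer_,
                          threshold = thr))
  }
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values)
  best <- ok[which.max(r$lengths[ok])]
  tibble::tibble(start_doy = starts[best], end_doy = ends[best],
                 threshold = thr)
}

#' Per-type snow dates from site phenology
#'
#' Aggregates site-year snow phenology to vegetation-type level: per-site
#' median snow-free and snow-onset DOY across years (default window
#' 2000-2020), then the mean across the type's sites.
#'
#' @param phenology output of [snow_phenology_table()].
#' @param metadata site table.
#' @param year_range inclusive year window for the site medians.
#' @return Tibble: `vegetation_type`, `snow_free_doy`, `snow_onset_doy`,
#'   `n_sites`.
#' @export
type_snow_dates <- function(phenology, metadata,
                            year_range = c(2000, 2020)) {
  phenology |>
    dplyr::filter(.data$year >= year_range[1], .data$year <= year_range[2]) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(snow_free_doy = median(.data$snow_free_doy, na.rm = TRUE),
                     snow_onset_doy = median(.data$snow_onset_doy,
                                             na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::inner_join(metadata[, c("site_id", "vegetation_type")],
                      by = "site_id") |>
    dplyr::group_by(.data$vegetation_type) |>
    dplyr::summarise(snow_free_doy = mean(.data$snow_free_doy, na.rm = TRUE),
                     snow_onset_doy = mean(.data$snow_onset_doy,
                                           na.rm = TRUE),
                     n_sites = dplyr::n(), .groups = "drop")
}

#' Summer-regime timing relative to snow phenology
#'
#' Detects the summer regime of each smoothed per-type curve and subtracts
#' the type's snow dates: `start_offset = start_doy - snow_free_doy`
#' (negative when the regime starts before snowmelt completes) and
#' `end_offset = end_doy - snow_onset_doy`.
#'
#' @param curves smoothed climatology (from [smooth_curves()]).
#' @param snow_dates per-type snow dates (from [type_snow_dates()]).
#' @param variables variables to detect regimes for (latent heat excluded).
#' @return Tibble: `vegetation_type`, `variable`, `start_doy`, `end_doy`,
#'   `snow_free_doy`, `snow_onset_doy`, `start_offset`, `end_offset`.
#' @export
regime_offsets <- function(curves, snow_dates,
                           variables = intersect(
                             c("R_net", "H", "G", "T_surf", "albedo"),
                             unique(curves$variable))) {
  curves |>
    dplyr::filter(.data$variable %in% variables) |>
    dplyr::group_by(.data$vegetation_type, .data$variable) |>
    dplyr::arrange(.data$doy, .by_group = TRUE) |>
    dplyr::reframe(detect_summer_regime(pad365(.data$mean, .data$doy),
                                        .data$variable[1])) |>
    dplyr::inner_join(snow_dates[, c("vegetation_type", "snow_free_doy",
                                     "snow_onset_doy")],
                      by = "vegetation_type") |>
    dplyr::mutate(start_offset = .data$start_doy - .data$snow_free_doy,
                  end_offset = .data$end_doy - .data$snow_onset_doy)
}

#' Welch two-sample t-test for regime-vs-snow timing
#'
#' Compares per-type summer-regime dates with per-type snow dates using a
#' two-sample Welch t-test (Satterthwaite degrees of freedom, two-sided).
#' When both groups are constant with equal means the statistic is defined
#' as 0 with p = 1.
#'
#' @param regime_doys numeric vector (one value per vegetation type).
#' @param snow_doys numeric vector.
#' @return One-row tibble: `t`, `df`, `p_value`, `mean_difference`.
#' @export
welch_offset_test <- function(regime_doys, snow_doys) {
  x <- regime_doys[!is.na(regime_doys)]
  y <- snow_doys[!is.na(snow_doys)]
  if (length(x) < 2 || length(y) < 2) {
    stop("need at least 2 values per group", call. = FALSE)
  }
  res <- tryCatch(t.test(x, y, var.equal = FALSE),
                  error = function(e) NULL)
  if (is.null(res)) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(tibble::tibble(t = 0, df = length(x) + length(y) - 2,
                            p_value = 1, mean_difference = 0))
    }
    stop("degenerate groups with unequal means", call. = FALSE)
  }
  tibble::tibble(t = unname(res$statistic), df = unname(res$parameter),
                 p_value = res$p.value,
                 mean_difference = mean(x) - mean(y))
}
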