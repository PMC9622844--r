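#' Annual-cycle and site profiles for the synthetic flux network
#'
#' Default per-vegetation-type generating parameters. Each non-shortwave
#' variable follows a cosine annual cycle in day of year,
#' `level + amplitude * cos(2*pi*(doy - peak_doy)/365)`; shortwave radiation
#' follows solar geometry with a fixed clear-sky transmissivity and a
#' snow-dependent albedo. Cycle levels and amplitudes are solved so that the
#' summer (JJA) and winter (DJF) means of each cycle hit per-type anchor
#' values chosen to mirror the magnitudes and orderings reported for Arctic
#' flux networks: boreal peat bog has the lowest summer Bowen ratio, the
#' shrub tundra types the highest among vegetated classes, and barren and
#' glacier surfaces act as summer heat sinks (negative H).
#'
#' Surface temperature is generated by inverting the longwave-out cycle
#' through the Stefan-Boltzmann law with emissivity 1, so that on noise-free
#' data the radiative identity
#' \eqn{R_{net} = SW_{in}(1-\alpha) + LW_{in} - \sigma T_{surf}^4}
#' holds exactly.
#'
#' @return A list with elements `cycles` (tibble: `vegetation_type`,
#'   `variable`, `level`, `amplitude`, `peak_doy`) and `types` (tibble of
#'   per-type albedo, snow-phenology and latitude parameters, plus
#'   `bowen_target`, the analytic JJA H / JJA LE ratio of the cycles).
#' @export
#' @examples
#' prof <- veg_profiles()
#' prof$types[, c("vegetation_type", "bowen_target")]
veg_profiles <- function() {
  peak <- 197 # mid-July flux peak
  # per-type anchors: JJA mean / DJF mean of the generating cycle
  anchors <- tibble::tribble(
    ~vegetation_type, ~H_jja, ~H_win, ~LE_jja, ~LE_win, ~G_jja, ~G_win,
    ~LW_out_jja, ~T_air_jja, ~T_air_win, ~summer_albedo,
    "barren",          -18, -35,  0, 0,  5, -8, 371,  4, -25, 0.20,
    "graminoid",        26, -25, 47, 2, 11, -8, 349,  8, -22, 0.15,
    "prostrate-shrub",  39, -25, 24, 2, 11, -8, 338,  6, -24, 0.16,
    "erect-shrub",      38, -25, 25, 2, 16, -8, 329,  9, -20, 0.15,
    "wetland",          34, -25, 32, 2, 11, -8, 339,  8, -20, 0.13,
    "boreal peat bog",   7, -20, 75, 2,  5, -8, 351, 13, -12, 0.12,
    "glacier",         -24, -28,  8, 0,  5, -5, 336,  0, -25, 0.60
  )
  cyc <- purrr::pmap_dfr(anchors, function(vegetation_type, H_jja, H_win,
                                           LE_jja, LE_win, G_jja, G_win,
                                           LW_out_jja, T_air_jja, T_air_win,
                                           summer_albedo) {
    specs <- list(
      H      = c(H_jja, H_win),
      LE     = c(LE_jja, LE_win),
      G      = c(G_jja, G_win),
      LW_in  = c(300, 230),
      LW_out = c(LW_out_jja, 255),
      T_air  = c(T_air_jja, T_air_win)
    )
    purrr::imap_dfr(specs, function(sw, nm) {
      p <- solve_cycle(sw[1], sw[2], peak)
      tibble::tibble(vegetation_type = vegetation_type, variable = nm,
                     level = p[["level"]], amplitude = p[["amplitude"]],
                     peak_doy = peak)
    })
  })
  types <- tibble::tibble(
    vegetation_type = anchors$vegetation_type,
    summer_albedo = anchors$summer_albedo,
    snow_albedo = ifelse(anchors$vegetation_type == "glacier", 0.75, 0.80),
    snow_free_doy_mean = c(165, 155, 160, 150, 150, 135, 190),
    snow_free_doy_sd = 6,
    snow_onset_doy_mean = c(270, 275, 272, 278, 276, 290, 240),
    snow_onset_doy_sd = 6,
    lat_min = c(70, 64, 70, 63, 62, 60, 61),
    lat_max = c(78, 72, 78, 70, 72, 64, 80)
  )
  types$bowen_target <- vapply(types$vegetation_type, function(v) {
    le <- cycle_seasonal_mean(cyc, v, "LE", JJA_DOYS)
    h <- cycle_seasonal_mean(cyc, v, "H", JJA_DOYS)
    if (abs(le) < 1e-9) NA_real_ else h / le
  }, numeric(1), USE.NAMES = FALSE)
  stopifnot(all(types$snow_free_doy_mean < types$snow_onset_doy_mean))
  list(cycles = cyc, types = types)
}

# Solve cosine level/amplitude so the JJA and DJF means hit the anchors
solve_cycle <- function(jja_target, winter_target, peak_doy) {
  cj <- mean(cos(2 * pi * (JJA_DOYS - peak_doy) / 365))
  cd <- mean(cos(2 * pi * (DJF_DOYS - peak_doy) / 365))
  amplitude <- (jja_target - winter_target) / (cj - cd)
  c(level = jja_target - amplitude * cj, amplitude = amplitude)
}

cycle_value <- function(doy, level, amplitude, peak_doy) {
  level + amplitude * cos(2 * pi * (doy - peak_doy) / 365)
}

#' Analytic seasonal mean of a generating cycle
#'
#' Closed-form mean of the noise-free generating cosine of one variable over
#' a set of days of year. Used as the independent oracle when checking that
#' the harmonization pipeline recovers the generator's true seasonal means.
#'
#' @param cycles the `cycles` tibble from [veg_profiles()] (or a `truth`
#'   element returned by [generate_network()]).
#' @param vegetation_type,variable which cycle.
#' @param doys integer days of year (default: June-August).
#' @return The mean of the cycle over `doys` (scalar).
#' @export
cycle_seasonal_mean <- function(cycles, vegetation_type, variable,
                                doys = JJA_DOYS) {
  row <- cycles[cycles$vegetation_type == vegetation_type &
                  cycles$variable == variable, ]
  if (nrow(row) != 1) {
    stop("no unique cycle for ", vegetation_type, " / ", variable)
  }
  mean(cycle_value(doys, row$level, row$amplitude, row$peak_doy))
}

#' Configuration for the synthetic flux network
#'
#' Validates and assembles the generator configuration. All fractions must
#' lie in `[0, 1]`, `timestep` must divide 1440 minutes and `years` must be
#' non-empty; violations raise an error naming the offending field. The same
#' configuration and seed always produce identical output.
#'
#' @param n_sites_per_vegtype sites generated per vegetation class.
#' @param years inclusive calendar-year vector.
#' @param timestep record spacing in minutes (30 or 60).
#' @param vegetation_types classes to generate (subset of
#'   [VEGETATION_TYPES]).
#' @param noise_sd named numeric vector of additive Gaussian noise standard
#'   deviations per variable (W m-2; degrees C for temperatures). Unnamed
#'   scalar recycles to all variables.
#' @param gap_fraction fraction of sub-daily slots removed in contiguous
#'   runs.
#' @param mean_gap_length_hours mean length of an injected gap run.
#' @param outlier_rate fraction of radiation/temperature records replaced by
#'   values beyond the quality-filter bounds (e.g. radiation > 1400 W m-2),
#'   so the filter's effect is observable.
#' @param gapfill_fraction fraction of records flagged `"gap-filled"` (these
#'   are excluded by [quality_filter()]).
#' @param replicate_probability probability a site carries a second
#'   replicated sensor.
#' @param overlap_fraction fraction of sites also distributed under a second
#'   network label with a small sensor offset.
#' @param network_labels candidate data-distribution networks.
#' @param transmissivity bulk atmospheric transmissivity applied to
#'   top-of-atmosphere shortwave.
#' @param seed integer RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sites_per_vegtype = 2,
                       years = 2001:2003,
                       timestep = 60,
                       vegetation_types = VEGETATION_TYPES,
                       noise_sd = c(SW_in = 30, SW_out = 15, LW_in = 15,
                                    LW_out = 10, H = 25, LE = 20, G = 8,
                                    T_air = 2, T_surf = 1.5),
                       gap_fraction = 0.05,
                       mean_gap_length_hours = 2,
                       outlier_rate = 0.001,
                       gapfill_fraction = 0.02,
                       replicate_probability = 0.25,
                       overlap_fraction = 0.2,
                       network_labels = c("AmeriFlux", "FLUXNET", "PROMICE"),
                       transmissivity = 0.65,
                       seed = 1L) {
  chk_frac <- function(x, nm) {
    if (!is.numeric(x) || any(x < 0) || any(x > 1)) {
      stop("invalid configuration: `", nm, "` must be a fraction in [0, 1]",
           call. = FALSE)
    }
  }
  chk_frac(gap_fraction, "gap_fraction")
  chk_frac(outlier_rate, "outlier_rate")
  chk_frac(gapfill_fraction, "gapfill_fraction")
  chk_frac(replicate_probability, "replicate_probability")
  chk_frac(overlap_fraction, "overlap_fraction")
  if (length(years) < 1) {
    stop("invalid configuration: `years` must be non-empty", call. = FALSE)
  }
  if (length(timestep) != 1 || timestep <= 0 || 1440 %% timestep != 0) {
    stop("invalid configuration: `timestep` must divide 1440 minutes",
         call. = FALSE)
  }
  if (!all(vegetation_types %in% VEGETATION_TYPES)) {
    stop("invalid configuration: `vegetation_types` must be a subset of ",
         paste(VEGETATION_TYPES, collapse = ", "), call. = FALSE)
  }
  if (mean_gap_length_hours <= 0) {
    stop("invalid configuration: `mean_gap_length_hours` must be positive",
         call. = FALSE)
  }
  if (is.null(names(noise_sd)) && length(noise_sd) == 1) {
    noise_sd <- setNames(rep(noise_sd, 9),
                         c(RADIATION_VARIABLES, HEAT_FLUX_VARIABLES,
                           TEMPERATURE_VARIABLES))
  }
  structure(list(n_sites_per_vegtype = n_sites_per_vegtype,
                 years = sort(unique(as.integer(years))),
                 timestep = as.integer(timestep),
                 vegetation_types = vegetation_types,
                 noise_sd = noise_sd,
                 gap_fraction = gap_fraction,
                 mean_gap_length_hours = mean_gap_length_hours,
                 outlier_rate = outlier_rate,
                 gapfill_fraction = gapfill_fraction,
                 replicate_probability = replicate_probability,
                 overlap_fraction = overlap_fraction,
                 network_labels = network_labels,
                 transmissivity = transmissivity,
                 seed = as.integer(seed)),
            class = "sim_config")
}

type_abbrev <- function(type) {
  c("barren" = "B", "graminoid" = "G", "prostrate-shrub" = "P",
    "erect-shrub" = "S", "wetland" = "W", "boreal peat bog" = "PB",
    "glacier" = "GL")[[type]]
}

unit_of <- function(variable) {
  dplyr::case_when(
    variable %in% TEMPERATURE_VARIABLES ~ "degC",
    variable == "precip" ~ "mm",
    TRUE ~ "W m-2"
  )
}

# Snow-weight in [0,1]: ~1 between snow-free and snow-onset, ~0 outside,
# with ~1-week logistic transitions
snow_free_weight <- function(doy, free_doy, onset_doy) {
  stats::plogis((doy - free_doy) / 3) * stats::plogis((onset_doy - doy) / 3)
}

sb_invert <- function(lw_out) (pmax(lw_out, 1) / SIGMA_SB)^0.25 - 273.15

#' Generate a synthetic multi-network flux-tower archive
#'
#' Generates sub-daily SEB observations for a circumpolar network of sites:
#' incoming shortwave follows solar geometry (zero when the sun is below the
#' horizon), reflected shortwave follows a snow-dependent albedo, and all
#' other variables follow the per-type annual cycles of [veg_profiles()]
#' with additive Gaussian noise. Sensor replication, overlapping
#' distribution networks, gap-filled flags, out-of-range outliers and
#' contiguous data gaps are injected per the configuration. Daily
#' snow-category and climate (air temperature, precipitation) series are
#' produced alongside, and the generating truth is returned for
#' parameter-recovery tests.
#'
#' @param config a [sim_config()].
#' @return A list:
#' \describe{
#'   \item{records}{long tibble of sub-daily records: `site_id`, `timestamp`
#'     (local standard time), `variable`, `value`, `qc_flag`, `network`,
#'     `replicate_id`, `unit`.}
#'   \item{metadata}{one row per site: coordinates, vegetation and CAVM
#'     classes, permafrost classes, cloud climatology, altitude, primary
#'     `network`.}
#'   \item{snow}{daily snow-category series: `site_id`, `date`, `snow`
#'     ("snow"/"no snow").}
#'   \item{climate}{daily `t_air` (degrees C) and `precip` (mm) per site.}
#'   \item{truth}{list of generating `cycles`, `types` and per-site-year
#'     snow transition days.}
#' }
#' @export
#' @examples
#' net <- generate_network(sim_config(n_sites_per_vegtype = 1,
#'                                    years = 2001, gap_fraction = 0))
#' dplyr::count(net$records, variable)
generate_network <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  prof <- veg_profiles()
  types <- prof$types[prof$types$vegetation_type %in%
                        config$vegetation_types, ]

  metadata <- purrr::pmap_dfr(types, function(vegetation_type, summer_albedo,
                                              snow_albedo, snow_free_doy_mean,
                                              snow_free_doy_sd,
                                              snow_onset_doy_mean,
                                              snow_onset_doy_sd,
                                              lat_min, lat_max, bowen_target) {
    n <- config$n_sites_per_vegtype
    lat <- runif(n, lat_min, lat_max)
    vt <- vegetation_type
    glacier <- vt == "glacier"
    subzone <- if (glacier) rep("G", n) else {
      as.character(cut(lat, c(-Inf, 64, 68, 72, 76, Inf),
                       labels = c("E", "D", "C", "B", "A")))
    }
    pf_extent <- if (glacier) rep("g", n) else {
      if (vegetation_type == "boreal peat bog") rep("Si", n) else
        ifelse(lat >= 70, "C", ifelse(lat >= 66, "D", "Si"))
    }
    pf_ice <- if (glacier) rep("g", n) else
      sample(c("h", "m", "l"), n, replace = TRUE)
    tibble::tibble(
      site_id = sprintf("%s%02d", type_abbrev(vegetation_type), seq_len(n)),
      vegetation_type = vt,
      latitude = lat,
      longitude = runif(n, -160, 60),
      altitude = if (glacier) runif(n, 300, 1500) else runif(n, 5, 400),
      cloud_cover = runif(n, 55, 75),
      cloud_temperature = runif(n, -40, -20),
      cavm_type = type_abbrev(vt),
      cavm_subzone = subzone,
      permafrost_extent = pf_extent,
      permafrost_ice = pf_ice,
      network = sample(config$network_labels, n, replace = TRUE)
    )
  })

  # snow transition draws per site-year: F = first "no snow" day in spring,
  # O = first "snow" day in autumn
  snow_truth <- tidyr::expand_grid(site_id = metadata$site_id,
                                   year = config$years) |>
    dplyr::left_join(metadata[, c("site_id", "vegetation_type")],
                     by = "site_id") |>
    dplyr::left_join(types[, c("vegetation_type", "snow_free_doy_mean",
                               "snow_free_doy_sd", "snow_onset_doy_mean",
                               "snow_onset_doy_sd")],
                     by = "vegetation_type")
  snow_truth$first_nosnow_doy <- round(rnorm(nrow(snow_truth),
                                             snow_truth$snow_free_doy_mean,
                                             snow_truth$snow_free_doy_sd))
  snow_truth$first_snow_doy <- round(rnorm(nrow(snow_truth),
                                           snow_truth$snow_onset_doy_mean,
                                           snow_truth$snow_onset_doy_sd))
  bad <- snow_truth$first_nosnow_doy >= snow_truth$first_snow_doy
  snow_truth$first_nosnow_doy[bad] <- snow_truth$snow_free_doy_mean[bad]
  snow_truth$first_snow_doy[bad] <- snow_truth$snow_onset_doy_mean[bad]
  snow_truth <- snow_truth[, c("site_id", "year", "vegetation_type",
                               "first_nosnow_doy", "first_snow_doy")]

  dates <- seq(as.Date(paste0(min(config$years), "-01-01")),
               as.Date(paste0(max(config$years), "-12-31")), by = "day")
  date_tbl <- tibble::tibble(date = dates,
                             year = as.integer(format(dates, "%Y")),
                             doy = as.integer(format(dates, "%j")))

  one_site <- function(meta_row) {
    veg <- meta_row$vegetation_type
    ty <- types[types$vegetation_type == veg, ]
    cyc <- prof$cycles[prof$cycles$vegetation_type == veg, ]
    st <- snow_truth[snow_truth$site_id == meta_row$site_id, ]
    day <- dplyr::left_join(date_tbl, st[, c("year", "first_nosnow_doy",
                                             "first_snow_doy")], by = "year")
    w <- snow_free_weight(day$doy, day$first_nosnow_doy, day$first_snow_doy)
    day$albedo <- ty$snow_albedo - (ty$snow_albedo - ty$summer_albedo) * w

    # daily snow categories: snow outside the snow-free window
    snow_series <- tibble::tibble(
      site_id = meta_row$site_id, date = day$date,
      snow = ifelse(day$doy >= day$first_nosnow_doy &
                      day$doy < day$first_snow_doy, "no snow", "snow")
    )
    cyv <- function(v) {
      r <- cyc[cyc$variable == v, ]
      cycle_value(day$doy, r$level, r$amplitude, r$peak_doy)
    }
    climate <- tibble::tibble(
      site_id = meta_row$site_id, date = day$date,
      t_air = cyv("T_air") + rnorm(nrow(day), 0, 1.5),
      precip = round(rgamma(nrow(day), shape = 0.4, scale = 3), 2)
    )

    slots_per_day <- as.integer(1440 / config$timestep)
    ts <- rep(day$date, each = slots_per_day)
    tod_min <- rep(seq(0, 1440 - config$timestep, by = config$timestep),
                   times = nrow(day))
    timestamp <- as.POSIXct(ts, tz = "UTC") + tod_min * 60
    idx_day <- rep(seq_len(nrow(day)), each = slots_per_day)
    doy <- day$doy[idx_day]
    hour <- tod_min / 60

    cosz <- cos_zenith(meta_row$latitude, doy, hour)
    e0 <- eccentricity_factor(doy)
    sw_clear <- SOLAR_CONSTANT * e0 * config$transmissivity * pmax(cosz, 0)
    nsd <- function(v) if (v %in% names(config$noise_sd))
      config$noise_sd[[v]] else 0
    up <- cosz > 0
    sw_in <- sw_clear
    sw_in[up] <- pmax(sw_in[up] + rnorm(sum(up), 0, nsd("SW_in")), 0)
    alb <- day$albedo[idx_day]
    sw_out <- alb * sw_in
    sw_out[up] <- pmax(sw_out[up] + rnorm(sum(up), 0, nsd("SW_out")), 0)

    n <- length(timestamp)
    vals <- list(
      SW_in = sw_in,
      SW_out = sw_out,
      LW_in = cyv("LW_in")[idx_day] + rnorm(n, 0, nsd("LW_in")),
      LW_out = cyv("LW_out")[idx_day] + rnorm(n, 0, nsd("LW_out")),
      H = cyv("H")[idx_day] + rnorm(n, 0, nsd("H")),
      LE = cyv("LE")[idx_day] + rnorm(n, 0, nsd("LE")),
      G = cyv("G")[idx_day] + rnorm(n, 0, nsd("G")),
      T_air = cyv("T_air")[idx_day] + rnorm(n, 0, nsd("T_air")),
      T_surf = sb_invert(cyv("LW_out")[idx_day]) + rnorm(n, 0, nsd("T_surf"))
    )
    rec <- purrr::imap_dfr(vals, function(v, nm) {
      tibble::tibble(site_id = meta_row$site_id, timestamp = timestamp,
                     variable = nm, value = v)
    })
    # outliers beyond the quality-filter bounds
    if (config$outlier_rate > 0) {
      is_rad <- rec$variable %in% RADIATION_VARIABLES
      hit <- is_rad & runif(nrow(rec)) < config$outlier_rate
      rec$value[hit] <- runif(sum(hit), 1450, 1800)
      is_tmp <- rec$variable %in% TEMPERATURE_VARIABLES
      hit_t <- is_tmp & runif(nrow(rec)) < config$outlier_rate
      rec$value[hit_t] <- -150
    }
    rec$qc_flag <- ifelse(runif(nrow(rec)) < config$gapfill_fraction,
                          "gap-filled", "measured")
    rec$network <- meta_row$network
    rec$replicate_id <- "r1"

    if (runif(1) < config$replicate_probability) {
      rep2 <- rec
      rep2$replicate_id <- "r2"
      offs <- rnorm(1, 0, 1)
      rep2$value <- rep2$value + offs + rnorm(nrow(rep2), 0, 2)
      rec <- dplyr::bind_rows(rec, rep2)
    }
    list(records = rec, snow = snow_series, climate = climate)
  }

  parts <- purrr::map(seq_len(nrow(metadata)),
                      function(i) one_site(metadata[i, ]))
  records <- dplyr::bind_rows(purrr::map(parts, "records"))
  snow <- dplyr::bind_rows(purrr::map(parts, "snow"))
  climate <- dplyr::bind_rows(purrr::map(parts, "climate"))

  # overlapping networks: duplicate a subset of sites under a second label
  n_overlap <- floor(config$overlap_fraction * nrow(metadata))
  if (n_overlap > 0 && length(config$network_labels) > 1) {
    dup_sites <- sample(metadata$site_id, n_overlap)
    dup <- records[records$site_id %in% dup_sites &
                     records$replicate_id == "r1", ]
    alt <- vapply(dup$network, function(nw) {
      setdiff(config$network_labels, nw)[1]
    }, character(1))
    dup$network <- alt
    dup$value <- dup$value + rnorm(nrow(dup), 0, 2)
    records <- dplyr::bind_rows(records, dup)
  }

  if (config$gap_fraction > 0) {
    records <- inject_gaps(records, config$gap_fraction,
                           config$mean_gap_length_hours,
                           timestep_minutes = config$timestep)
  }
  records$unit <- unit_of(records$variable)
  records <- dplyr::arrange(records, .data$site_id, .data$network,
                            .data$replicate_id, .data$variable,
                            .data$timestamp)

  list(records = records, metadata = metadata, snow = snow, climate = climate,
       truth = list(cycles = prof$cycles, types = types,
                    site_snow = snow_truth))
}

#' Remove contiguous runs of sub-daily records
#'
#' Deletes approximately `gap_fraction` of the slots of every
#' (site, network, replicate, variable) stream in contiguous runs whose
#' lengths are geometric with the stated mean, stress-testing the downstream
#' completeness and maximum-gap rules.
#'
#' @param records sub-daily record tibble (see [generate_network()]).
#' @param gap_fraction fraction of slots to remove, in `[0, 1]`.
#' @param mean_gap_length_hours mean contiguous gap length in hours.
#' @param seed optional RNG seed for reproducible removal.
#' @param timestep_minutes record spacing, used to convert hours to slots.
#' @return The records tibble with the selected rows removed.
#' @export
inject_gaps <- function(records, gap_fraction, mean_gap_length_hours = 2,
                        seed = NULL, timestep_minutes = 60) {
  if (gap_fraction < 0 || gap_fraction > 1) {
    stop("`gap_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (mean_gap_length_hours <= 0) {
    stop("`mean_gap_length_hours` must be positive", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (gap_fraction == 0) return(records)
  if (gap_fraction == 1) return(records[0, ])
  mean_slots <- max(1, mean_gap_length_hours * 60 / timestep_minutes)

  grp <- paste(records$site_id, records$network, records$replicate_id,
               records$variable, sep = "\r")
  keep <- rep(TRUE, nrow(records))
  for (idx in split(seq_len(nrow(records)), grp)) {
    n <- length(idx)
    target <- round(gap_fraction * n)
    removed <- logical(n)
    guard <- 0L
    while (sum(removed) < target && guard < 10L * n) {
      start <- sample.int(n, 1)
      len <- 1L + stats::rgeom(1, 1 / mean_slots)
      removed[start:min(n, start + len - 1L)] <- TRUE
      guard <- guard + 1L
    }
    keep[idx[removed]] <- FALSE
  }
  records[keep, ]
}

#' Canonical SEB-driver and response names
#'
#' The 15 site-level drivers (5 categorical, 10 numeric) and the 14 seasonal
#' flux responses (8 measured/derived + 6 potential-shortwave-normalized)
#' used by the variance-partitioning analysis.
#'
#' @export
DRIVER_NAMES <- c("vegetation_type", "cavm_type", "cavm_subzone",
                  "permafrost_extent", "permafrost_ice", "temperature",
                  "summer_warmth", "continentality", "precipitation",
                  "snow_amount", "snow_duration", "cloud_cover",
                  "cloud_temperature", "latitude", "altitude")

#' @rdname DRIVER_NAMES
#' @export
RESPONSE_NAMES <- c("R_net", "H", "LE", "G", "SW_net", "LW_net",
                    "albedo", "T_surf",
                    "n.R_net", "n.SW_net", "n.LW_net", "n.H", "n.LE", "n.G")

#' Simulate a site-level driver/response table with a dominant driver
#'
#' Builds a table of the 15 canonical drivers plus seasonal flux responses in
#' which vegetation type contributes a known multiple (`dominance`) of the
#' response variance of every other driver. Drivers are mutually independent
#' so the generating variance components are the oracle for
#' driver-importance recovery tests against [run_all_pairs()].
#'
#' @param n_sites number of sites (rows).
#' @param seed RNG seed.
#' @param dominance ratio of the vegetation-type variance contribution to
#'   each other driver's contribution (must be >= 1). The default (16, with
#'   per-driver contribution sd 0.5 and noise sd 1) gives vegetation type a
#'   generating variance share near one half, emulating the dominant role it
#'   plays for the turbulent fluxes in real networks.
#' @param responses which response columns to simulate (default all 14).
#' @return Tibble with `site_id`, the 15 driver columns and the requested
#'   response columns; the generating standard deviations are attached as
#'   attribute `"truth"`.
#' @export
simulate_driver_response <- function(n_sites = 35, seed = 1,
                                     dominance = 16,
                                     responses = RESPONSE_NAMES) {
  set.seed(seed)
  k <- 5
  lev <- c("graminoid", "prostrate-shrub", "erect-shrub", "wetland",
           "boreal peat bog")
  drv <- tibble::tibble(
    site_id = sprintf("S%03d", seq_len(n_sites)),
    vegetation_type = factor(sample(lev, n_sites, replace = TRUE)),
    cavm_type = factor(sample(c("G", "P", "S", "W"), n_sites, TRUE)),
    cavm_subzone = factor(sample(c("C", "D", "E"), n_sites, TRUE)),
    permafrost_extent = factor(sample(c("C", "D", "Si"), n_sites, TRUE)),
    permafrost_ice = factor(sample(c("h", "m", "l"), n_sites, TRUE))
  )
  num <- setdiff(DRIVER_NAMES, names(drv))
  for (v in num) drv[[v]] <- rnorm(n_sites)

  sd_other <- 0.5
  sd_type <- sqrt(dominance) * sd_other
  type_eff <- rnorm(k, 0, 1)
  type_eff <- (type_eff - mean(type_eff)) / sd(type_eff) * sd_type
  cat_eff <- function(f) {
    e <- rnorm(nlevels(f))
    e <- (e - mean(e)) / sd(e) * sd_other
    e[as.integer(f)]
  }
  base <- type_eff[as.integer(drv$vegetation_type)] +
    cat_eff(drv$cavm_type) + cat_eff(drv$cavm_subzone) +
    cat_eff(drv$permafrost_extent) + cat_eff(drv$permafrost_ice) +
    rowSums(sapply(num, function(v) drv[[v]] * sd_other))
  for (r in responses) drv[[r]] <- base + rnorm(n_sites, 0, 1)
  attr(drv, "truth") <- list(sd_type = sd_type, sd_other = sd_other,
                             sd_noise = 1)
  drv
}
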