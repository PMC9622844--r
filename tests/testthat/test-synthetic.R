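test_that("configuration validation names the offending field", {
  expect_error(sim_config(gap_fraction = 1.5), "gap_fraction")
  expect_error(sim_config(outlier_rate = -0.1), "outlier_rate")
  expect_error(sim_config(timestep = 77), "timestep")
  expect_error(sim_config(years = integer(0)), "years")
  expect_error(sim_config(vegetation_types = "rainforest"),
               "vegetation_types")
  expect_error(sim_config(mean_gap_length_hours = 0), "mean_gap_length")
})

test_that("same seed and config give byte-identical output", {
  cfg <- sim_config(n_sites_per_vegtype = 1, years = 2001,
                    vegetation_types = c("wetland", "glacier"), seed = 7)
  a <- generate_network(cfg)
  b <- generate_network(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$snow, b$snow)
  cfg2 <- sim_config(n_sites_per_vegtype = 1, years = 2001,
                     vegetation_types = c("wetland", "glacier"), seed = 8)
  expect_false(identical(generate_network(cfg2)$records, a$records))
})

test_that("incoming shortwave follows solar geometry: zero below horizon", {
  net <- generate_network(sim_config(
    n_sites_per_vegtype = 1, years = 2001, vegetation_types = "graminoid",
    gap_fraction = 0, outlier_rate = 0, seed = 3))
  sw <- dplyr::filter(net$records, variable == "SW_in",
                      replicate_id == "r1")
  lat <- net$metadata$latitude[1]
  doy <- as.integer(format(sw$timestamp, "%j"))
  hr <- as.integer(format(sw$timestamp, "%H")) +
    as.integer(format(sw$timestamp, "%M")) / 60
  cz <- cos_zenith(lat, doy, hr)
  expect_true(all(sw$value >= 0))
  expect_true(all(sw$value[cz <= 0] == 0))
  expect_true(any(sw$value[cz > 0] > 0))
})

test_that("noise-free summer Bowen ratio matches the profile target within 1%", {
  net <- generate_network(noise_free_config(
    types = c("graminoid", "boreal peat bog", "erect-shrub")))
  daily <- harmonize_daily(net$records, timestep_minutes = 60)
  sm <- seasonal_site_means(daily, "JJA", responses = c("H", "LE"))
  smw <- seasonal_site_means_wide(sm)
  smw <- dplyr::inner_join(smw, net$metadata[, c("site_id",
                                                 "vegetation_type")],
                           by = "site_id")
  for (i in seq_len(nrow(smw))) {
    target <- net$truth$types$bowen_target[
      net$truth$types$vegetation_type == smw$vegetation_type[i]]
    expect_equal(smw$H[i] / smw$LE[i], target, tolerance = 0.01)
  }
  # ordering: peat bog lowest, shrubs highest among vegetated types
  bt <- veg_profiles()$types
  veg <- bt[!bt$vegetation_type %in% c("barren", "glacier"), ]
  expect_equal(veg$vegetation_type[which.min(veg$bowen_target)],
               "boreal peat bog")
  top2 <- veg$vegetation_type[order(-veg$bowen_target)][1:2]
  expect_setequal(top2, c("prostrate-shrub", "erect-shrub"))
})

test_that("snow series is consistent with the generating transition days", {
  net <- generate_network(sim_config(n_sites_per_vegtype = 2, years = 2001,
                                     vegetation_types = c("wetland",
                                                          "graminoid"),
                                     seed = 11))
  snow <- dplyr::mutate(net$snow,
                        year = as.integer(format(date, "%Y")),
                        doy = as.integer(format(date, "%j")))
  joined <- dplyr::inner_join(snow, net$truth$site_snow,
                              by = c("site_id", "year"))
  inside <- joined$doy >= joined$first_nosnow_doy &
    joined$doy < joined$first_snow_doy
  expect_true(all(joined$snow[inside] == "no snow"))
  expect_true(all(joined$snow[!inside] == "snow"))
})

test_that("pipeline recovers the generating summer LE mean within 2 noise s.e.", {
  sd_le <- 20
  cfg <- sim_config(n_sites_per_vegtype = 1, years = 2001:2002,
                    vegetation_types = c("graminoid", "boreal peat bog",
                                         "wetland"),
                    noise_sd = c(LE = sd_le),
                    gap_fraction = 0, outlier_rate = 0,
                    gapfill_fraction = 0, replicate_probability = 0,
                    overlap_fraction = 0, seed = 21)
  net <- generate_network(cfg)
  daily <- harmonize_daily(net$records, timestep_minutes = 60)
  sm <- seasonal_site_means(daily, "JJA", responses = "LE")
  meta <- net$metadata
  n_obs <- 2 * length(arcticseb:::JJA_DOYS) * 24 # slots entering the mean
  se <- sd_le / sqrt(n_obs)
  for (i in seq_len(nrow(sm))) {
    veg <- meta$vegetation_type[meta$site_id == sm$site_id[i]]
    truth <- cycle_seasonal_mean(net$truth$cycles, veg, "LE")
    expect_lt(abs(sm$value[i] - truth), 2 * se + 1e-9)
  }
})

test_that("gap injection honors its limits and reproduces by seed", {
  rec <- make_day_records(1:48, timestep = 30)
  expect_identical(inject_gaps(rec, 0, timestep_minutes = 30), rec)
  expect_equal(nrow(inject_gaps(rec, 1, timestep_minutes = 30)), 0)
  expect_error(inject_gaps(rec, 0.1, mean_gap_length_hours = -2), "positive")
  expect_error(inject_gaps(rec, 1.3), "gap_fraction")

  long <- dplyr::bind_rows(lapply(0:59, function(d) {
    make_day_records(1:48, timestep = 30,
                     date = as.Date("2010-06-01") + d)
  }))
  g1 <- inject_gaps(long, 0.1, mean_gap_length_hours = 6, seed = 5,
                    timestep_minutes = 30)
  g2 <- inject_gaps(long, 0.1, mean_gap_length_hours = 6, seed = 5,
                    timestep_minutes = 30)
  expect_identical(g1, g2)
  removed <- 1 - nrow(g1) / nrow(long)
  expect_gt(removed, 0.05)
  expect_lt(removed, 0.2)
})

test_that("long gaps make a measurable share of days fail the 4.8 h rule", {
  long <- dplyr::bind_rows(lapply(0:59, function(d) {
    make_day_records(1:48, timestep = 30, date = as.Date("2010-06-01") + d)
  }))
  gapped <- inject_gaps(long, 0.1, mean_gap_length_hours = 6, seed = 9,
                        timestep_minutes = 30)
  # oracle: direct per-day slot scan of the post-injection records
  slot_of <- function(ts) {
    (as.integer(format(ts, "%H")) * 60 + as.integer(format(ts, "%M"))) %/%
      30 + 1
  }
  by_day <- split(slot_of(gapped$timestamp), as.Date(gapped$timestamp))
  oracle_admit <- vapply(by_day, admit_day_oracle, logical(1),
                         timestep = 30)
  expect_gt(sum(!oracle_admit), 0)
  daily <- aggregate_daily(gapped, timestep_minutes = 30)
  expect_setequal(as.character(daily$date),
                  names(oracle_admit)[oracle_admit])
})
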