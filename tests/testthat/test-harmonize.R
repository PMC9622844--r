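test_that("quality filter applies each removal rule with correct counts", {
  rec <- tibble::tibble(
    site_id = "A",
    timestamp = as.POSIXct("2010-06-01", tz = "UTC") + 3600 * (0:9),
    variable = c("SW_in", "LW_out", "H", "LE", "albedo", "albedo",
                 "T_air", "T_surf", "SW_in", "G"),
    value = c(1500, -5, -300, 40, 1.2, 0.5, -150, 10, 800, -20),
    qc_flag = c(rep("measured", 9), "gap-filled")
  )
  out <- quality_filter(rec)
  log <- removal_log(out)
  expect_equal(log$n_removed[log$rule == "radiation_gt_1400"], 1) # SW_in 1500
  expect_equal(log$n_removed[log$rule == "radiation_negative"], 1) # LW_out -5
  expect_equal(log$n_removed[log$rule == "albedo_outside_0_1"], 1)
  expect_equal(log$n_removed[log$rule == "temperature_lt_minus100"], 1)
  expect_equal(log$n_removed[log$rule == "gap_filled"], 1)
  # negative turbulent flux retained; in-range values retained
  expect_true(any(out$variable == "H" & out$value == -300))
  expect_true(any(out$variable == "albedo" & out$value == 0.5))
  expect_equal(nrow(out), 5)
})

test_that("quality filter is idempotent and rejects unknown variables", {
  rec <- tibble::tibble(site_id = "A",
                        timestamp = as.POSIXct("2010-06-01", tz = "UTC"),
                        variable = "SW_in", value = 500,
                        qc_flag = "measured")
  once <- quality_filter(rec)
  twice <- quality_filter(once)
  expect_equal(as.data.frame(once), as.data.frame(twice))
  bad <- dplyr::mutate(rec, variable = "WINDSPEED")
  expect_error(quality_filter(bad), "WINDSPEED")
  expect_error(quality_filter(bad), "accepted")
})

test_that("flux sign convention flips heat fluxes exactly once", {
  rec <- tibble::tibble(site_id = "A",
                        timestamp = as.POSIXct("2010-06-01", tz = "UTC"),
                        variable = c("H", "LE", "G", "SW_in"),
                        value = c(10, -20, 5, 300), qc_flag = "measured")
  away <- harmonize_flux_sign(rec, from = "toward")
  expect_equal(away$value, c(-10, 20, -5, 300))
  # round trip restores the original declaration
  expect_equal(harmonize_flux_sign(away, from = "toward")$value, rec$value)
  expect_equal(harmonize_flux_sign(rec, from = "away")$value, rec$value)
})

test_that("daily admission follows the 65% completeness and 4.8 h gap rules", {
  # 32/48 slots in one contiguous block: completeness 66.7% but 8 h gap
  d1 <- aggregate_daily(make_day_records(1:32, timestep = 30),
                        timestep_minutes = 30)
  expect_equal(nrow(d1), 0)
  # 39/48 slots with the largest gap 9 slots (4.5 h): retained
  slots <- setdiff(1:48, 20:28)
  d2 <- aggregate_daily(make_day_records(slots, timestep = 30),
                        timestep_minutes = 30)
  expect_equal(nrow(d2), 1)
  expect_equal(d2$completeness, 39 / 48)
  expect_equal(d2$max_gap_hours, 4.5)
  # 10 consecutive missing slots (5 h): rejected even at high completeness
  d3 <- aggregate_daily(make_day_records(setdiff(1:48, 20:29),
                                         timestep = 30),
                        timestep_minutes = 30)
  expect_equal(nrow(d3), 0)
  # below 65% completeness: rejected despite short gaps
  scattered <- seq(1, 48, by = 2)[1:24] # 50%, max gap 30 min
  d4 <- aggregate_daily(make_day_records(scattered, timestep = 30),
                        timestep_minutes = 30)
  expect_equal(nrow(d4), 0)
  # complete constant day: mean = min = max = v
  d5 <- aggregate_daily(make_day_records(1:48, value = 7.5, timestep = 30),
                        timestep_minutes = 30)
  expect_equal(c(d5$mean, d5$min, d5$max), c(7.5, 7.5, 7.5))
})

test_that("admission agrees with a brute-force slot scan on a random battery", {
  withr::local_seed(14)
  for (k in 1:25) {
    n_present <- sample(20:48, 1)
    slots <- sort(sample(1:48, n_present))
    day <- aggregate_daily(make_day_records(slots, timestep = 30),
                           timestep_minutes = 30)
    expect_equal(nrow(day) == 1, admit_day_oracle(slots, timestep = 30),
                 info = paste("slots:", paste(slots, collapse = ",")))
  }
})

test_that("off-grid timestamps are rejected as mixed timesteps", {
  rec <- make_day_records(1:24, timestep = 60)
  rec$timestamp[3] <- rec$timestamp[3] + 7 * 60
  expect_error(aggregate_daily(rec, timestep_minutes = 60), "grid")
})

test_that("replicates average within network before networks average", {
  day <- as.Date("2010-06-01")
  r1 <- make_day_records(1:24, value = 10, timestep = 60, network = "N1",
                         replicate_id = "r1", date = day)
  r2 <- make_day_records(1:24, value = 20, timestep = 60, network = "N1",
                         replicate_id = "r2", date = day)
  n2 <- make_day_records(1:24, value = 40, timestep = 60, network = "N2",
                         replicate_id = "r1", date = day)
  out <- aggregate_daily(dplyr::bind_rows(r1, r2, n2), timestep_minutes = 60)
  # within-network replicate mean 15, then cross-network mean of {15, 40}
  expect_equal(out$mean, 27.5)
  # an incomplete replicate is dropped before averaging
  r2_bad <- make_day_records(1:10, value = 1000, timestep = 60,
                             network = "N1", replicate_id = "r2", date = day)
  out2 <- aggregate_daily(dplyr::bind_rows(r1, r2_bad, n2),
                          timestep_minutes = 60)
  expect_equal(out2$mean, 25)
})

test_that("radiation derivation follows the stated definitions and guards", {
  daily <- tibble::tibble(site_id = "A", date = as.Date("2010-06-01"),
                          SW_in = 200, SW_out = 40, LW_in = 300,
                          LW_out = 350)
  out <- derive_radiation(daily)
  expect_equal(out$SW_net, 160)
  expect_equal(out$LW_net, -50)
  expect_equal(out$R_net, 110)
  expect_equal(out$albedo, 0.20)
  # polar night / low sun: albedo undefined below the shortwave floor
  night <- derive_radiation(dplyr::mutate(daily, SW_in = 0, SW_out = 0))
  expect_true(is.na(night$albedo))
  dusk <- derive_radiation(dplyr::mutate(daily, SW_in = 5, SW_out = 4))
  expect_true(is.na(dusk$albedo))
  # measured net radiation is preserved, missing entries filled
  two <- tibble::tibble(site_id = "A",
                        date = as.Date("2010-06-01") + 0:1,
                        SW_in = 200, SW_out = 40, LW_in = 300, LW_out = 350,
                        R_net = c(105, NA))
  out2 <- derive_radiation(two)
  expect_equal(out2$R_net, c(105, 110))
  # conservation wherever all three exist
  expect_equal(out2$SW_net + out2$LW_net, c(110, 110))
})

test_that("noise-free synthetic data satisfies the radiative-budget identity", {
  net <- generate_network(noise_free_config(types = "wetland"))
  daily <- harmonize_daily(net$records, timestep_minutes = 60)
  ok <- !is.na(daily$albedo) & !is.na(daily$R_net) & !is.na(daily$T_surf)
  d <- daily[ok, ]
  # emissivity 1: R_net = SW_in (1 - albedo) + LW_in - sigma T_surf^4
  lhs <- d$R_net
  sigma <- 5.670374419e-8
  rhs <- d$SW_in * (1 - d$albedo) + d$LW_in - sigma * (d$T_surf + 273.15)^4
  expect_gt(nrow(d), 50)
  expect_lt(max(abs(lhs - rhs)), 1e-6)
  # and the net-radiation identity holds exactly
  expect_equal(d$R_net, d$SW_net + d$LW_net)
})
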