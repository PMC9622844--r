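test_that("climatology reduces to site values and two-site s.e.", {
  dates <- seq(as.Date("2005-01-01"), as.Date("2005-12-31"), by = "day")
  daily <- dplyr::bind_rows(
    tibble::tibble(site_id = "A", date = dates, H = 10),
    tibble::tibble(site_id = "B", date = dates, H = 30)
  )
  meta <- tibble::tibble(site_id = c("A", "B"),
                         vegetation_type = "wetland")
  cl <- doy_climatology(daily, meta, variables = "H", year_min = 2000)
  expect_equal(nrow(cl), 365)
  expect_equal(unique(cl$mean), 20)       # (a + b) / 2
  expect_equal(unique(cl$se), 10)         # |a - b| / 2 for n = 2
  expect_equal(unique(cl$n_sites), 2)
  one <- doy_climatology(daily[daily$site_id == "A", ], meta,
                         variables = "H")
  expect_equal(unique(one$mean), 10)
  expect_equal(unique(one$se), 0)
})

test_that("Feb 29 is dropped so all years map onto a 365-day axis", {
  dates <- seq(as.Date("2004-01-01"), as.Date("2004-12-31"), by = "day")
  daily <- tibble::tibble(site_id = "A", date = dates,
                          H = seq_along(dates))
  meta <- tibble::tibble(site_id = "A", vegetation_type = "graminoid")
  cl <- doy_climatology(daily, meta, variables = "H")
  expect_equal(nrow(cl), 365)
  expect_equal(max(cl$doy), 365)
  # Mar 1 of the leap year (value 61) lands on DOY 60
  expect_equal(cl$mean[cl$doy == 60], 61)
})

test_that("15-day smoothing is linear, mean-preserving and phase-preserving", {
  expect_equal(smooth_15d(rep(3.2, 365)), rep(3.2, 365))
  # single-day spike spreads to 15 days of height h/15
  spike <- rep(0, 365); spike[100] <- 30
  sm <- smooth_15d(spike)
  expect_equal(sm[93:107], rep(2, 15))
  expect_equal(sum(sm > 0), 15)
  # annual harmonic: amplitude scaled by the Dirichlet factor, no phase shift
  d <- 1:365
  x <- cos(2 * pi * (d - 40) / 365)
  theta <- 2 * pi / 365
  factor <- sin(15 * theta / 2) / (15 * sin(theta / 2))
  expect_equal(smooth_15d(x), factor * x, tolerance = 1e-10)
  # mean preservation on an arbitrary complete circular series
  withr::local_seed(6)
  z <- rnorm(365)
  expect_equal(mean(smooth_15d(z)), mean(z), tolerance = 1e-12)
})

test_that("summer regime matches the analytic zero crossings of a harmonic", {
  d <- 1:365
  curve <- 100 * sin(2 * pi * (d - 81) / 365)
  reg <- detect_summer_regime(smooth_15d(curve), "R_net")
  # analytic crossings at DOY 81 (up) and 263.5 (down)
  expect_lte(abs(reg$start_doy - 81), 1)
  expect_lte(abs(reg$end_doy - 263.5), 1)
  # invariant to positive rescaling
  reg2 <- detect_summer_regime(smooth_15d(0.01 * curve), "R_net")
  expect_equal(reg2[, 1:2], reg[, 1:2])
})

test_that("regime edge cases: full-year, absent, and albedo orientation", {
  expect_equal(detect_summer_regime(rep(5, 365), "H")$start_doy, 1)
  expect_equal(detect_summer_regime(rep(5, 365), "H")$end_doy, 365)
  none <- detect_summer_regime(rep(-5, 365), "G")
  expect_true(is.na(none$start_doy))
  expect_error(detect_summer_regime(rep(5, 365), "LE"), "latent")
  # albedo step: summer is BELOW the midpoint threshold
  alb <- c(rep(0.9, 150), rep(0.1, 130), rep(0.9, 85))
  reg <- detect_summer_regime(smooth_15d(alb), "albedo")
  expect_equal(reg$threshold, 0.5)
  expect_lte(abs(reg$start_doy - 151), 7)
  expect_lte(abs(reg$end_doy - 280), 7)
  # affine rescaling leaves the albedo regime unchanged
  reg2 <- detect_summer_regime(smooth_15d(0.5 * alb + 0.2), "albedo")
  expect_equal(reg2[, 1:2], reg[, 1:2])
})

test_that("offsets subtract snow dates with the documented sign convention", {
  curves <- tibble::tibble(
    vegetation_type = "wetland", variable = "R_net", doy = 1:365,
    mean = ifelse(1:365 >= 95 & 1:365 <= 280, 10, -10)
  )
  snow_dates <- tibble::tibble(vegetation_type = "wetland",
                               snow_free_doy = 151, snow_onset_doy = 275)
  off <- regime_offsets(curves, snow_dates)
  expect_equal(off$start_offset, 95 - 151) # -56: regime leads snowmelt
  expect_equal(off$end_offset, 280 - 275)
  same <- regime_offsets(dplyr::mutate(curves,
                                       mean = ifelse(doy >= 151 & doy <= 275,
                                                     10, -10)),
                         snow_dates)
  expect_equal(same$start_offset, 0)
})

test_that("Welch test handles degenerate and equal-variance limits", {
  same <- welch_offset_test(c(3, 3, 3), c(3, 3, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  # equal variances: Welch statistic equals the pooled Student statistic
  x <- c(1, 2, 3); y <- c(11, 12, 13)
  ours <- welch_offset_test(x, y)
  pooled <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours$t, unname(pooled$statistic), tolerance = 1e-12)
  expect_equal(ours$df, unname(pooled$parameter), tolerance = 1e-12)
  expect_error(welch_offset_test(1, c(1, 2)), "at least 2")
})

test_that("type-level curves recover generator cycles and regime timing", {
  net <- generate_network(noise_free_config(types = c("wetland",
                                                      "erect-shrub"),
                                            years = 2001:2002))
  daily <- harmonize_daily(net$records, timestep_minutes = 60)
  cl <- doy_climatology(daily, net$metadata, variables = c("H", "G"),
                        year_min = 2000)
  sm <- smooth_curves(cl)
  # climatology equals the generating cosine up to the smoothing factor
  h_wet <- sm[sm$vegetation_type == "wetland" & sm$variable == "H", ]
  truth <- vapply(h_wet$doy, function(dd) {
    cyc <- net$truth$cycles
    r <- cyc[cyc$vegetation_type == "wetland" & cyc$variable == "H", ]
    r$level + r$amplitude * cos(2 * pi * (dd - r$peak_doy) / 365)
  }, numeric(1))
  expect_lt(max(abs(h_wet$mean - truth)), 1.5) # smoothing attenuation only
  # detected start within a day of the analytic cycle zero crossing
  reg <- detect_summer_regime(h_wet$mean[order(h_wet$doy)], "H")
  r <- net$truth$cycles[net$truth$cycles$vegetation_type == "wetland" &
                          net$truth$cycles$variable == "H", ]
  cross <- r$peak_doy - 365 / (2 * pi) * acos(-r$level / r$amplitude)
  expect_lte(abs(reg$start_doy - cross), 1.5)
})
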