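# Builders for small in-memory fixtures used across the suite.

# One site-day of sub-daily records on a regular grid. `slots` are the
# 1-based present slot indices of a `timestep`-minute day.
make_day_records <- function(slots, value = 100, variable = "H",
                             timestep = 30, date = as.Date("2010-06-01"),
                             site_id = "SITE", network = "NET",
                             replicate_id = "r1", qc_flag = "measured") {
  stopifnot(all(slots >= 1), all(slots <= 1440 / timestep))
  ts <- as.POSIXct(date, tz = "UTC") + (slots - 1) * timestep * 60
  tibble::tibble(site_id = site_id, timestamp = ts, variable = variable,
                 value = value, qc_flag = qc_flag, network = network,
                 replicate_id = replicate_id)
}

# Oracle for the daily completeness / maximum-gap admission rule: a direct
# slot scan, independent of aggregate_daily()'s implementation.
admit_day_oracle <- function(slots, timestep = 30,
                             min_completeness = 0.65, max_gap_hours = 4.8) {
  nominal <- 1440 / timestep
  present <- sort(unique(slots))
  completeness <- length(present) / nominal
  missing <- setdiff(seq_len(nominal), present)
  runs <- if (length(missing) == 0) 0 else {
    r <- rle(seq_len(nominal) %in% missing)
    max(c(0, r$lengths[r$values]))
  }
  completeness >= min_completeness && runs * timestep / 60 <= max_gap_hours
}

# Independent R-squared oracle: explicit normal-equations projection.
r2_oracle <- function(y, X) {
  X <- cbind(1, X)
  beta <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% beta
  1 - sum(res^2) / sum((y - mean(y))^2)
}

# A small noise-free network configuration (deterministic pipeline checks).
noise_free_config <- function(types = c("graminoid", "boreal peat bog"),
                              years = 2001, seed = 42) {
  sim_config(n_sites_per_vegtype = 1, years = years, timestep = 60,
             vegetation_types = types,
             noise_sd = c(SW_in = 0, SW_out = 0, LW_in = 0, LW_out = 0,
                          H = 0, LE = 0, G = 0, T_air = 0, T_surf = 0),
             gap_fraction = 0, outlier_rate = 0, gapfill_fraction = 0,
             replicate_probability = 0, overlap_fraction = 0, seed = seed)
}

# Fixed 10-site toy table for the variance-partition oracle comparison.
toy_varpart_table <- function() {
  tibble::tibble(
    site_id = sprintf("T%02d", 1:10),
    y = c(12.1, 9.4, 15.2, 7.7, 11.3, 14.8, 8.2, 10.6, 13.9, 9.9),
    a = c(1.2, 0.4, 2.1, -0.3, 0.9, 1.8, 0.1, 0.7, 1.6, 0.5),
    b = c(0.3, -1.1, 0.8, -0.6, 1.4, 0.2, -0.9, 0.5, 1.1, -0.2)
  )
}
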