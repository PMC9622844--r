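#!/usr/bin/env Rscript
# Stage 4: rank SEB-driver importance for summer flux magnitudes with the
# all-pairs variance-partitioning scheme (vegetation subset: glacier sites
# excluded). At this synthetic scale several categorical pairs are skipped
# for aliasing; the per-driver summaries aggregate the pairs that fit.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "_common.R"))

daily <- readr::read_csv(results_path("daily_harmonized.csv"),
                         show_col_types = FALSE)
drivers <- readr::read_csv(results_path("drivers.csv"),
                           show_col_types = FALSE)

site_means <- seasonal_site_means(daily, "JJA")
wide <- seasonal_site_means_wide(site_means) |>
  inner_join(drivers, by = "site_id") |>
  filter(vegetation_type != "glacier")
site_years <- site_means |>
  distinct(site_id, n_years) |>
  (\(d) setNames(d$n_years, d$site_id))()

vp <- suppressWarnings(run_all_pairs(wide, site_years = site_years))
cat("Evaluated", attr(vp, "n_model_evaluations"), "ordered 2-predictor",
    "models over", attr(vp, "n_pairs_unique"), "driver pairs per response\n")
for (resp in c("LE", "H")) {
  cat("\nTop drivers for summer", resp, ":\n")
  print(head(rank_drivers(vp, resp)[, c("driver", "mean_explained",
                                        "min_explained", "max_explained")],
             5))
}
readr::write_csv(vp, results_path("varpart.csv"))
readr::write_csv(attr(vp, "counts"), results_path("varpart_counts.csv"))
cat("\nWrote varpart.csv and varpart_counts.csv under results/\n")
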