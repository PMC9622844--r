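#!/usr/bin/env Rscript
# Stage 3: compute the 15 site-level SEB drivers from metadata, climate and
# snow series (continentality, summer warmth, snow amount/duration computed
# here; the rest carried from site metadata).

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "_common.R"))

metadata <- readr::read_csv(results_path("metadata.csv"),
                            show_col_types = FALSE)
climate <- readr::read_csv(results_path("climate.csv"),
                           show_col_types = FALSE)
snow <- readr::read_csv(results_path("snow.csv"), show_col_types = FALSE)

drivers <- build_driver_table(metadata, climate, snow)
print(drivers, width = Inf)
readr::write_csv(drivers, results_path("drivers.csv"))
cat("Wrote drivers.csv (", nrow(drivers), "sites x 15 drivers )\n")
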