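#!/usr/bin/env Rscript
# Stage 1: generate the synthetic circumpolar flux network and write the
# site-level inputs (metadata, snow categories, climate) for later stages.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "_common.R"))

net <- study_network()

cat("Simulated", nrow(net$metadata), "sites across",
    length(unique(net$metadata$vegetation_type)), "vegetation classes,",
    length(STUDY_CONFIG$years), "years,",
    nrow(net$records), "sub-daily records\n")
print(count(net$records, network))
print(count(net$metadata, vegetation_type))

readr::write_csv(net$metadata, results_path("metadata.csv"))
readr::write_csv(net$snow, results_path("snow.csv"))
readr::write_csv(net$climate, results_path("climate.csv"))
readr::write_csv(net$truth$cycles, results_path("truth_cycles.csv"))
cat("Wrote metadata.csv, snow.csv, climate.csv, truth_cycles.csv",
    "under results/\n")
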