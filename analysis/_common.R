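# Shared study configuration for the analysis scripts. The synthetic study
# follows the structure of the circumpolar observation archive: all seven
# land-cover classes, overlapping distribution networks, replicated sensors,
# gaps and outliers, at hourly resolution over a three-year span.

library(arcticseb)
suppressPackageStartupMessages(library(dplyr))

STUDY_SEED <- 20260926
STUDY_CONFIG <- sim_config(n_sites_per_vegtype = 2, years = 2001:2003,
                           timestep = 60, seed = STUDY_SEED)

results_path <- function(...) {
  dir.create("results", showWarnings = FALSE)
  file.path("results", ...)
}

study_network <- function() generate_network(STUDY_CONFIG)
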