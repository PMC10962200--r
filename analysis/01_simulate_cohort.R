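#!/usr/bin/env Rscript
# Simulate the study cohorts: 15 paediatric-like and 15 adult-like patients,
# 6-20 samples each over 785-1166 days, under the two between-sample overlap
# regimes. Writes the standard input TSVs (taxa table, manifest, clinical
# table) for each regime under results/data/.

suppressPackageStartupMessages(library(lungturnover))
seed <- 20240901

for (regime in c("drift", "homogenizing")) {
  cfg <- generator_config(regime = regime)
  co <- generate_cohort(cfg, seed = seed)
  out <- file.path("results", "data", regime)
  paths <- write_cohort_dataset(co, out)
  n_samp <- vapply(co$series, function(s) nrow(s$samples), numeric(1))
  span <- vapply(co$series, function(s) max(s$samples$collection_day), numeric(1))
  message(sprintf(
    "%s regime: %d patients, %d samples (%d-%d per patient), spans %d-%d days -> %s",
    regime, length(co$series), sum(n_samp), min(n_samp), max(n_samp),
    min(span), max(span), out))
}
message("done; downstream scripts read results/data/drift by default")
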