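#!/usr/bin/env Rscript
# Partition each patient's taxa into chronic (> 50 % persistence) and
# intermittent (<= 50 %) colonizers and fit the persistence-abundance
# relationship (PAR) per patient. Writes results/persistence.tsv and
# results/par_fits.tsv and prints the cohort richness summaries.

suppressPackageStartupMessages(library(lungturnover))

ds <- read_taxa_table("results/data/drift/taxa_table.tsv",
                      "results/data/drift/manifest.tsv")
md <- read_clinical_metadata("results/data/drift/clinical.tsv")
ds <- cohort_dataset(ds$series, md)
incl <- apply_inclusion_criteria(ds)
if (nrow(incl$exclusions)) print(incl$exclusions) else
  message("all ", length(incl$dataset$series), " patients meet the inclusion criteria")
ds <- incl$dataset

records <- lapply(ds$series, function(s)
  partition_leeds(taxon_persistence(s)))

pers <- do.call(rbind, lapply(names(records), function(p)
  cbind(patient_id = p, records[[p]])))
dir.create("results", showWarnings = FALSE)
write.table(pers, "results/persistence.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

par_fits <- do.call(rbind, lapply(names(records), function(p) {
  f <- fit_par(records[[p]])
  data.frame(patient_id = p, slope = f$slope, r2 = f$r2, F = f$F, p = f$p,
             n_taxa = f$n_taxa)
}))
write.table(par_fits, "results/par_fits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("PAR positive and significant in %d/%d patients",
                sum(par_fits$slope > 0 & par_fits$p < 0.05), nrow(par_fits)))
for (what in c("total", "chronic", "intermittent")) {
  v <- vapply(records, function(r) switch(what,
      total = nrow(r), sum(r$status == what)), numeric(1))
  sm <- cohort_summaries(stats::setNames(v, names(records)), md)
  message(sprintf("%s richness: paediatric %.1f +/- %.1f, adult %.1f +/- %.1f",
                  what,
                  sm$mean[sm$label == "paediatric"], sm$sd[sm$label == "paediatric"],
                  sm$mean[sm$label == "adult"], sm$sd[sm$label == "adult"]))
}
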