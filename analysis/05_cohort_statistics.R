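#!/usr/bin/env Rscript
# Cohort-level statistics. On the study's clinical table: the paediatric vs
# adult lung-function contrast (Kruskal-Wallis) and the regression of
# exacerbation count on mean %FEV1. On the simulated cohort: regressions of
# whole-microbiota process frequencies on lung function per cohort. Writes
# results/cohort_statistics.json.

suppressPackageStartupMessages(library(lungturnover))

stats_out <- list()

## the study's 30 patients --------------------------------------------------
md <- table1_fixture()
fev1 <- split(md$mean_fev1, md$cohort)
kw <- kruskal_wallis(list(paediatric = fev1$paediatric, adult = fev1$adult))
ols <- simple_ols(md$mean_fev1, md$exacerbations)
message(sprintf("study cohorts: paediatric %%FEV1 %.1f +/- %.1f, adult %.1f +/- %.1f",
                mean(fev1$paediatric), sd(fev1$paediatric),
                mean(fev1$adult), sd(fev1$adult)))
message(sprintf("lung function paediatric vs adult: H = %.2f, p = %.3f", kw$H, kw$p))
message(sprintf("exacerbations ~ %%FEV1: R2 = %.2f, F(1,%d) = %.1f, p = %.2g",
                ols$r2, ols$df[2], ols$F, ols$p))
stats_out$study <- list(
  fev1 = lapply(fev1, function(v) list(mean = mean(v), sd = sd(v), n = length(v))),
  fev1_kruskal = list(H = kw$H, p = kw$p),
  exacerbations_vs_fev1 = list(slope = ols$slope, r2 = ols$r2, F = ols$F, p = ols$p))

## simulated cohort: processes vs lung function ------------------------------
fr <- read.delim("results/process_frequencies.tsv")
clin <- read_clinical_metadata("results/data/drift/clinical.tsv")
wm <- fr[fr$group == "microbiota" & fr$regime == "drift",
         c("patient_id", "pct_homogenizing", "pct_drift")]
regs <- process_lungfunction_regressions(wm, clin)
for (co in names(regs)) {
  message(sprintf(
    "%s: %%FEV1 vs homogenizing slope %.2f (p = %.2f); vs drift slope %.2f (p = %.2f)",
    co, regs[[co]]$homogenizing$slope, regs[[co]]$homogenizing$p,
    regs[[co]]$drift$slope, regs[[co]]$drift$p))
}
stats_out$simulated <- lapply(regs, function(co) lapply(co, function(f)
  list(slope = f$slope, r2 = f$r2, F = f$F, p = f$p)))

jsonlite::write_json(stats_out, "results/cohort_statistics.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote results/cohort_statistics.json")
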