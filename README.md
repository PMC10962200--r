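# lungturnover

Ecology of temporal turnover in longitudinal airway microbiota.

People with cystic fibrosis carry a lung microbiota that is resampled at
every clinic visit over years. Which taxa are resident and which are
transient? How fast does the community turn over, and is that turnover driven
by deterministic dispersal or by stochastic drift? And do the inferred
processes relate to lung function? `lungturnover` implements that analysis
for per-patient taxa-by-time relative-abundance tables, for microbiome
researchers and biostatisticians working with longitudinal 16S cohorts.

The pipeline:

* **Chronic/intermittent partition (modified Leeds criteria).** A taxon with
  persistence (percentage of a patient's samples in which it is detected)
  strictly above 50 % is a chronic colonizer; at or below 50 % it is
  intermittent.
* **Persistence-abundance relationships (PAR).** OLS of persistence (%) on
  log10 mean relative abundance over the samples where the taxon was
  detected — the temporal analogue of an occupancy-abundance relationship.
* **Species-time relationships (STR).** Moving-window construction: each
  adjacent sample pair contributes a point with S = |union of the two
  presence sets| and T = elapsed days; the power law S = cT^w is fitted on
  log-log axes. The exponent w is the temporal turnover rate.
* **Raup-Crick process attribution.** For every within-patient sample pair,
  the observed shared-taxa count is compared to a Monte-Carlo null (1000
  randomizations) assembling both communities at observed richness from the
  occurrence-weighted regional species pool; with p the null probability of
  less overlap (ties half-weighted), s_RC = 2p − 1 ∈ [−1, 1]. Pairs with
  s_RC ≥ 0.95 are homogenizing dispersal, ≤ −0.95 dispersal limitation,
  otherwise ecological drift.
* **Cohort statistics.** Tie-corrected Kruskal-Wallis with Dunn post-hoc
  tests, simple OLS (F = r²/(1−r²)·(n−2)), cohort means ± sample SD, and
  regressions of process frequencies on %FEV1.
* **Synthetic cohorts.** A generator that emulates the study envelope (6-20
  samples over 785-1166 days, resident core vs rare transients, %FEV1
  inversely linked to exacerbations) under two overlap regimes
  (template-based "homogenizing" vs Markov "drift"), so the whole pipeline is
  testable without sequencing data.

## Worked example

```r
library(lungturnover)

cfg <- generator_config()                 # study-like defaults, drift regime
cohort <- generate_cohort(cfg, seed = 20240901)
series <- cohort$series[["p01"]]

records <- partition_leeds(taxon_persistence(series))
table(records$status)
#>      chronic intermittent
#>           20           27

fit_par(records)
#> PAR fit (n = 47 taxa, log10 abundance): slope = 19.5, R2 = 0.823,
#> F(1,45) = 209, p = 1.57e-18

strs <- str_for_groups(series, records)
sapply(strs$fits, function(f) f$w)
#>  microbiota      chronic intermittent
#> 0.031387204  0.004689843  0.082527715
```

Persistence rises with abundance (positive PAR), and intermittent colonizers
turn over an order of magnitude faster than the chronic core. Running the
whole cohort through `run_pipeline()` (or the step-wise scripts below) adds
the Raup-Crick attribution; on this simulated cohort the chronic group reads
as homogenizing dispersal in every patient while the intermittent group is
drift-dominated (mean 84 % of pairs), matching the ecology the generator
encodes.

On the packaged clinical table of the 30 study patients:

```r
md <- table1_fixture()
kruskal_wallis(split(md$mean_fev1, md$cohort))
#> Kruskal-Wallis: H = 4.388, df = 1, p = 0.0362 (n = 15, 15)
simple_ols(md$mean_fev1, md$exacerbations)
#> OLS: slope = -0.06661, R2 = 0.383, F(1,28) = 17.4, p = 0.000265
```

Adult lung function is significantly lower than paediatric, and exacerbation
counts fall with %FEV1.

## Analysis workflow

The `analysis/` scripts run the study end to end on a simulated cohort,
writing tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R      # cohorts under both regimes
Rscript analysis/02_persistence_partition.R
Rscript analysis/03_temporal_turnover.R
Rscript analysis/04_assembly_processes.R   # 1000 randomizations/pair
Rscript analysis/05_cohort_statistics.R
```

`vignettes/temporal-turnover-methods.Rmd` documents the models, defaults,
numerical choices, and the generator's design and limits.

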