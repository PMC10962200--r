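test_that("taxa tables load into per-patient normalized series", {
  dir <- write_toy_cohort_files()
  ds <- read_taxa_table(file.path(dir, "taxa_table.tsv"),
                        file.path(dir, "manifest.tsv"))
  expect_s3_class(ds, "cohort_dataset")
  expect_setequal(names(ds$series), c("P1", "P2"))
  # all-zero rows dropped per patient: P1 keeps 4 taxa, P2 keeps 3
  expect_equal(length(ds$series$P1$taxa), 4)
  expect_equal(length(ds$series$P2$taxa), 3)
  expect_false("A" %in% ds$series$P2$taxa)
  # counts (10, 30, 60) normalize to (0.1, 0.3, 0.6)
  expect_equal(unname(ds$series$P1$abundance[c("A", "C", "D"), 1]),
               c(0.1, 0.3, 0.6))
  # every column sums to one
  for (s in ds$series)
    expect_equal(unname(colSums(s$abundance)), rep(1, ncol(s$abundance)),
                 tolerance = 1e-9)
  # samples strictly ordered by day, day 0 first
  expect_equal(ds$series$P1$samples$collection_day, c(0, 30, 60))
})

test_that("loader validates manifests and abundances", {
  dir <- write_toy_cohort_files()
  tab <- file.path(dir, "taxa_table.tsv")
  man <- utils::read.delim(file.path(dir, "manifest.tsv"))

  # manifest lists a sample absent from the table -> error naming it
  man2 <- rbind(man, data.frame(sample_id = "s99", patient_id = "P2",
                                collection_day = 90, sample_type = "sputum"))
  f2 <- tempfile(); utils::write.table(man2, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_taxa_table(tab, f2), "s99")

  # sample in table but not in manifest -> error naming it
  man3 <- man[man$sample_id != "s5", ]
  f3 <- tempfile(); utils::write.table(man3, f3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_taxa_table(tab, f3), "s5")

  # negative collection day
  man4 <- man; man4$collection_day[2] <- -3
  f4 <- tempfile(); utils::write.table(man4, f4, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_taxa_table(tab, f4), "negative")

  # duplicate sample id
  man5 <- rbind(man, man[1, ])
  f5 <- tempfile(); utils::write.table(man5, f5, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_taxa_table(tab, f5), "duplicate")

  # same-day samples rejected unless merged
  man6 <- man; man6$collection_day[2] <- 0
  f6 <- tempfile(); utils::write.table(man6, f6, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_taxa_table(tab, f6), "same day")
  merged <- read_taxa_table(tab, f6, merge_same_day = TRUE)
  expect_equal(nrow(merged$series$P1$samples), 2)
  expect_equal(unname(colSums(merged$series$P1$abundance)), c(1, 1))

  # non-numeric abundance
  bad <- utils::read.delim(tab, check.names = FALSE)
  bad$s1[2] <- "oops"
  f7 <- tempfile(); utils::write.table(bad, f7, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_taxa_table(f7, file.path(dir, "manifest.tsv")), "non-numeric")
})

test_that("ISO dates convert to days since each patient's first sample", {
  dir <- write_toy_cohort_files()
  man <- utils::read.delim(file.path(dir, "manifest.tsv"))
  man$collection_day <- c("2020-01-01", "2020-01-31", "2020-03-01",
                          "2020-02-10", "2020-03-21")
  f <- tempfile(); utils::write.table(man, f, sep = "\t", quote = FALSE, row.names = FALSE)
  ds <- read_taxa_table(file.path(dir, "taxa_table.tsv"), f)
  expect_equal(ds$series$P1$samples$collection_day, c(0, 30, 60))
  expect_equal(ds$series$P2$samples$collection_day, c(0, 40))
})

test_that("BIOM tables load through the same validation path", {
  skip_if_not_installed("biomformat")
  m <- matrix(c(10, 0, 30, 0, 20, 40), 2, 3, byrow = TRUE,
              dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
  f <- tempfile(fileext = ".biom")
  suppressWarnings(biomformat::write_biom(biomformat::make_biom(m), f))
  man <- data.frame(sample_id = c("s1", "s2", "s3"), patient_id = "P1",
                    collection_day = c(0, 30, 60), sample_type = "sputum")
  mf <- tempfile()
  utils::write.table(man, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  ds <- read_biom_table(f, mf)
  expect_equal(unname(ds$series$P1$abundance["A", ]), c(1, 0, 30 / 70))
  expect_equal(unname(colSums(ds$series$P1$abundance)), c(1, 1, 1))
})

test_that("clinical metadata reader types and validates records", {
  md <- table1_fixture()
  expect_equal(nrow(md), 30)
  expect_equal(unname(table(md$cohort)["paediatric"]), 15L)
  expect_equal(unname(table(md$cohort)["adult"]), 15L)
  expect_equal(md$mean_fev1[md$patient_id == "110"], 120.1)
  expect_equal(md$exacerbations[md$patient_id == "106"], 8L)
  expect_equal(md$mean_fev1[md$patient_id == "216"], 117.8)

  f <- tempfile(); writeLines("patient_id\tcohort\tmean_fev1\tfev1_sd\texacerbations", f)
  expect_error(read_clinical_metadata(f), "no records")
  f2 <- tempfile(); writeLines(c("patient_id\tcohort\tmean_fev1",
                                 "1\tadult\t80"), f2)
  expect_error(read_clinical_metadata(f2), "missing column")
  f3 <- tempfile()
  writeLines(c("patient_id\tcohort\tmean_fev1\tfev1_sd\texacerbations",
               "1\tadult\tnotanumber\t2\t1"), f3)
  expect_error(read_clinical_metadata(f3), "unparseable")
})

test_that("inclusion criteria drop short or sparse series and are idempotent", {
  mk <- function(id, n, last) {
    days <- c(0, sort(sample(seq_len(last - 1), n - 2)), last)
    make_series(matrix(1, 2, n), days, id)
  }
  set.seed(1)
  ds <- cohort_dataset(list(mk("few", 5, 900), mk("short", 8, 730),
                            mk("ok", 6, 785)))
  res <- apply_inclusion_criteria(ds)
  expect_setequal(names(res$dataset$series), "ok")
  expect_equal(res$exclusions$reason[res$exclusions$patient_id == "few"],
               "too few samples")
  # day 730 is exactly the boundary: <= 730 days is excluded
  expect_equal(res$exclusions$reason[res$exclusions$patient_id == "short"],
               "duration")
  again <- apply_inclusion_criteria(res$dataset)
  expect_identical(names(again$dataset$series), names(res$dataset$series))
  expect_equal(nrow(again$exclusions), 0)
})

test_that("write then read reproduces a cohort", {
  cfg <- generator_config(n_patients = 2)
  co <- generate_cohort(cfg, seed = 21)
  dir <- tempfile()
  write_cohort_dataset(co, dir)
  back <- read_taxa_table(file.path(dir, "taxa_table.tsv"),
                          file.path(dir, "manifest.tsv"))
  md <- read_clinical_metadata(file.path(dir, "clinical.tsv"))
  expect_setequal(md$patient_id, names(co$series))
  for (pid in names(co$series)) {
    a <- co$series[[pid]]; b <- back$series[[pid]]
    expect_identical(colnames(a$abundance), colnames(b$abundance))
    expect_setequal(a$taxa, b$taxa)
    expect_lt(max(abs(a$abundance - b$abundance[a$taxa, ])), 1e-12)
    expect_identical(a$samples$collection_day, b$samples$collection_day)
  }
})

test_that("write_results emits the fixed schemas deterministically", {
  cfg <- generator_config(n_patients = 2)
  co <- generate_cohort(cfg, seed = 3)
  r <- run_pipeline(co, rc_iterations = 100, seed = 5, verbose = FALSE)
  d1 <- tempfile(); d2 <- tempfile()
  write_results(r, d1); write_results(r, d2)
  files <- c("persistence.tsv", "str_points.tsv", "str_fits.tsv",
             "raup_crick_pairs.tsv", "process_frequencies.tsv",
             "cohort_summary.json")
  expect_setequal(list.files(d1), files)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  expect_named(utils::read.delim(file.path(d1, "persistence.tsv"), nrows = 1),
               c("patient_id", "taxon_id", "n_samples_detected",
                 "n_samples_total", "persistence_pct",
                 "mean_rel_abund_detected", "status"))
  expect_named(utils::read.delim(file.path(d1, "str_points.tsv"), nrows = 1),
               c("patient_id", "group", "window_start_sample", "T_days", "S_taxa"))
  expect_named(utils::read.delim(file.path(d1, "raup_crick_pairs.tsv"), nrows = 1),
               c("patient_id", "group", "sample_a", "sample_b", "s_rc", "process"))

  # empty bundle -> summary JSON only
  d3 <- tempfile()
  write_results(list(), d3)
  expect_identical(list.files(d3), "cohort_summary.json")
})
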