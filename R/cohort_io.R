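#' Construct a per-patient taxa time series
#'
#' A `taxa_time_series` holds one patient's taxa-by-timepoint relative
#' abundance matrix together with the sampling schedule. Columns are sorted by
#' collection day (day 0 is the patient's first sample) and each column sums
#' to one; taxa never detected in this patient are dropped.
#'
#' @param patient_id Patient identifier.
#' @param abundance Numeric matrix, taxa in rows (rownames = taxon ids),
#'   samples in columns (colnames = sample ids). Counts or relative
#'   abundances; columns are normalized to sum to 1.
#' @param samples Data frame with columns `sample_id`, `collection_day` and
#'   optionally `sample_type` (one row per column of `abundance`).
#' @param normalize Normalize columns to relative abundance (default `TRUE`).
#' @return An object of class `taxa_time_series` with elements `patient_id`,
#'   `taxa`, `samples`, and `abundance`.
#' @export
taxa_time_series <- function(patient_id, abundance, samples, normalize = TRUE) {
  if (!is.matrix(abundance)) abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("abundance matrix needs taxon rownames and sample colnames")
  if (!all(c("sample_id", "collection_day") %in% names(samples)))
    stop("samples needs columns sample_id and collection_day")
  samples$sample_id <- as.character(samples$sample_id)
  if (is.null(samples$sample_type)) samples$sample_type <- "sputum"
  ok_type <- samples$sample_type %in% c("sputum", "cough_swab")
  if (!all(ok_type))
    stop("unknown sample_type: ", paste(unique(samples$sample_type[!ok_type]), collapse = ", "))
  if (!setequal(samples$sample_id, colnames(abundance)))
    stop("sample ids in manifest and abundance columns differ for patient ", patient_id)
  samples <- samples[match(colnames(abundance), samples$sample_id), , drop = FALSE]

  if (anyNA(abundance) || !is.numeric(abundance))
    stop("non-numeric abundance for patient ", patient_id)
  if (any(abundance < 0)) stop("negative abundance for patient ", patient_id)
  day <- samples$collection_day
  if (anyNA(day)) stop("missing collection_day for patient ", patient_id)
  if (any(day < 0)) stop("negative collection_day for patient ", patient_id)
  if (anyDuplicated(day))
    stop("two samples on the same day for patient ", patient_id,
         " (use merge_same_day on load)")
  # days are relative to the patient's first sample
  day <- day - min(day)
  samples$collection_day <- day
  ord <- order(day)
  samples <- samples[ord, , drop = FALSE]
  abundance <- abundance[, ord, drop = FALSE]

  csum <- colSums(abundance)
  if (any(csum == 0))
    stop("all-zero sample column for patient ", patient_id, ": ",
         paste(samples$sample_id[csum == 0], collapse = ", "))
  if (normalize) abundance <- sweep(abundance, 2, csum, "/")

  keep <- rowSums(abundance) > 0
  abundance <- abundance[keep, , drop = FALSE]
  rownames(samples) <- NULL
  structure(
    list(patient_id = as.character(patient_id),
         taxa = rownames(abundance),
         samples = samples,
         abundance = abundance),
    class = "taxa_time_series")
}

#' @export
print.taxa_time_series <- function(x, ...) {
  cat("taxa_time_series: patient", x$patient_id, "-", length(x$taxa), "taxa,",
      nrow(x$samples), "samples over",
      max(x$samples$collection_day), "days\n")
  invisible(x)
}

#' Presence/absence matrix of a series
#'
#' @param series A `taxa_time_series`.
#' @param detection_min Minimum relative abundance counted as a detection
#'   (strict inequality; default 0, i.e. any nonzero abundance).
#' @return Logical matrix, taxa x samples.
#' @export
presence_matrix <- function(series, detection_min = 0) {
  series$abundance > detection_min
}

#' Assemble a cohort dataset
#'
#' @param series Named list of [taxa_time_series()] objects (names = patient
#'   ids).
#' @param metadata Optional clinical table as returned by
#'   [read_clinical_metadata()]. When supplied, patients must match the series
#'   one-to-one.
#' @return An object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(series, metadata = NULL) {
  ids <- vapply(series, function(s) s$patient_id, character(1))
  names(series) <- ids
  if (anyDuplicated(ids)) stop("duplicate patient ids")
  all_samples <- unlist(lapply(series, function(s) s$samples$sample_id))
  if (anyDuplicated(all_samples))
    stop("duplicate sample_id across the study: ",
         paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "))
  if (!is.null(metadata)) {
    missing_meta <- setdiff(ids, metadata$patient_id)
    extra_meta <- setdiff(metadata$patient_id, ids)
    if (length(missing_meta))
      stop("patients without clinical metadata: ", paste(missing_meta, collapse = ", "))
    if (length(extra_meta))
      stop("clinical metadata for unknown patients: ", paste(extra_meta, collapse = ", "))
    metadata <- metadata[match(ids, metadata$patient_id), , drop = FALSE]
    rownames(metadata) <- NULL
  }
  structure(list(series = series, metadata = metadata), class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("cohort_dataset:", length(x$series), "patients",
      if (!is.null(x$metadata)) "(with clinical metadata)" else "(no metadata)", "\n")
  invisible(x)
}

#' Read a longitudinal taxa table and its sample manifest
#'
#' The taxa table is a TSV with taxon ids in the first column (`taxon_id`) and
#' one column per sample; entries may be counts or relative abundances and are
#' normalized per column. The manifest maps samples to patients and collection
#' days.
#'
#' @param table_path Path to the taxa table TSV.
#' @param manifest_path Path to the manifest TSV with columns `sample_id`,
#'   `patient_id`, `collection_day` (integer days or ISO dates) and
#'   `sample_type` (`sputum`/`cough_swab`).
#' @param merge_same_day Union two same-day samples of one patient by
#'   averaging their relative abundances instead of rejecting them.
#' @return A `cohort_dataset` without clinical metadata.
#' @export
read_taxa_table <- function(table_path, manifest_path, merge_same_day = FALSE) {
  tab <- utils::read.delim(table_path, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("taxa table needs a taxon_id column plus sample columns")
  taxa <- as.character(tab[[1]])
  if (anyDuplicated(taxa)) stop("duplicate taxon_id in taxa table")
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric abundance values in taxa table")
  rownames(mat) <- taxa

  man <- utils::read.delim(manifest_path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("sample_id", "patient_id", "collection_day", "sample_type")
  miss <- setdiff(need, names(man))
  if (length(miss)) stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(man$sample_id))
    stop("duplicate sample_id in manifest: ",
         paste(unique(man$sample_id[duplicated(man$sample_id)]), collapse = ", "))

  unknown <- setdiff(colnames(mat), man$sample_id)
  if (length(unknown))
    stop("sample(s) in taxa table missing from manifest: ",
         paste(unknown, collapse = ", "))
  absent <- setdiff(man$sample_id, colnames(mat))
  if (length(absent))
    stop("manifest sample(s) absent from taxa table: ",
         paste(absent, collapse = ", "))

  man$collection_day <- parse_collection_day(man$collection_day, man$patient_id)

  series <- lapply(split(man, man$patient_id), function(m) {
    sub <- mat[, m$sample_id, drop = FALSE]
    if (merge_same_day && anyDuplicated(m$collection_day)) {
      # union same-day samples by averaging normalized columns
      sub <- sweep(sub, 2, pmax(colSums(sub), .Machine$double.xmin), "/")
      grp <- match(m$collection_day, unique(m$collection_day))
      merged <- vapply(seq_along(unique(m$collection_day)), function(g)
        rowMeans(sub[, grp == g, drop = FALSE]), numeric(nrow(sub)))
      colnames(merged) <- m$sample_id[!duplicated(m$collection_day)]
      sub <- merged
      m <- m[!duplicated(m$collection_day), , drop = FALSE]
    }
    taxa_time_series(m$patient_id[1], sub,
                     m[, c("sample_id", "collection_day", "sample_type")])
  })
  cohort_dataset(series)
}

# integer days, or ISO dates converted to days since each patient's first
parse_collection_day <- function(x, patient_id) {
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) {
    if (any(num != round(num))) stop("collection_day must be whole days")
    if (any(num < 0)) stop("negative collection_day in manifest")
    return(as.integer(num))
  }
  d <- as.Date(x, format = "%Y-%m-%d")
  if (anyNA(d)) stop("collection_day values neither integer days nor ISO dates: ",
                     paste(unique(x[is.na(d) & is.na(num)]), collapse = ", "))
  unsplit(lapply(split(d, patient_id), function(dd) as.integer(dd - min(dd))),
          patient_id)
}

#' Read a taxa table in BIOM format
#'
#' Optional alternative to the TSV reader for BIOM (JSON or HDF5) tables;
#' requires the `biomformat` package.
#'
#' @inheritParams read_taxa_table
#' @param biom_path Path to a BIOM file.
#' @return A `cohort_dataset` without clinical metadata.
#' @export
read_biom_table <- function(biom_path, manifest_path, merge_same_day = FALSE) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("the biomformat package is required to read BIOM tables")
  b <- biomformat::read_biom(biom_path)
  mat <- as.matrix(biomformat::biom_data(b))
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.table(data.frame(taxon_id = rownames(mat), mat,
                                check.names = FALSE),
                     tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  read_taxa_table(tmp, manifest_path, merge_same_day = merge_same_day)
}

#' Read the patient clinical table
#'
#' @param path TSV with columns `patient_id`, `cohort`
#'   (`paediatric`/`adult`), `mean_fev1` (% predicted FEV1 averaged over the
#'   study), `fev1_sd`, and `exacerbations` (count over the study).
#' @return Data frame of typed clinical records.
#' @export
read_clinical_metadata <- function(path) {
  md <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("patient_id", "cohort", "mean_fev1", "fev1_sd", "exacerbations")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(md) == 0) stop("no records in clinical table ", path)
  md$patient_id <- as.character(md$patient_id)
  bad_cohort <- setdiff(unique(md$cohort), c("paediatric", "adult"))
  if (length(bad_cohort)) stop("unknown cohort label(s): ", paste(bad_cohort, collapse = ", "))
  for (col in c("mean_fev1", "fev1_sd", "exacerbations")) {
    v <- suppressWarnings(as.numeric(md[[col]]))
    if (anyNA(v)) stop("unparseable ", col, " in clinical table")
    md[[col]] <- v
  }
  if (any(md$mean_fev1 <= 0)) stop("mean_fev1 must be positive")
  if (any(md$fev1_sd < 0)) stop("fev1_sd must be non-negative")
  if (any(md$exacerbations < 0 | md$exacerbations != round(md$exacerbations)))
    stop("exacerbations must be non-negative integers")
  md$exacerbations <- as.integer(md$exacerbations)
  md[, need]
}

#' Apply the study inclusion criteria
#'
#' Patients contributing fewer than `min_samples` samples, or whose sampling
#' span does not reach `min_duration_days` (default 731, i.e. strictly more
#' than 730 days, extending into a third year), are excluded.
#'
#' @param dataset A `cohort_dataset`.
#' @param min_samples Minimum number of samples (default 6).
#' @param min_duration_days Minimum value of the last collection day
#'   (default 731).
#' @return List with `dataset` (the filtered `cohort_dataset`) and
#'   `exclusions` (data frame of `patient_id`, `reason`).
#' @export
apply_inclusion_criteria <- function(dataset, min_samples = 6,
                                     min_duration_days = 731) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  reasons <- lapply(dataset$series, function(s) {
    r <- character(0)
    if (nrow(s$samples) < min_samples) r <- c(r, "too few samples")
    if (max(s$samples$collection_day) < min_duration_days) r <- c(r, "duration")
    r
  })
  excluded <- names(reasons)[lengths(reasons) > 0]
  exclusions <- data.frame(
    patient_id = excluded,
    reason = vapply(reasons[excluded], paste, character(1), collapse = "; "),
    stringsAsFactors = FALSE)
  keep <- setdiff(names(dataset$series), excluded)
  md <- dataset$metadata
  if (!is.null(md)) md <- md[md$patient_id %in% keep, , drop = FALSE]
  filtered <- structure(list(series = dataset$series[keep], metadata = md),
                        class = "cohort_dataset")
  list(dataset = filtered, exclusions = exclusions)
}

#' Write a cohort dataset back to the standard input TSVs
#'
#' Writes `taxa_table.tsv`, `manifest.tsv` and (when metadata are present)
#' `clinical.tsv` so that a generated or filtered cohort can be re-read with
#' [read_taxa_table()] / [read_clinical_metadata()].
#'
#' @param dataset A `cohort_dataset`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all_taxa <- sort(unique(unlist(lapply(dataset$series, function(s) s$taxa))))
  cols <- lapply(dataset$series, function(s) {
    m <- matrix(0, length(all_taxa), ncol(s$abundance),
                dimnames = list(all_taxa, colnames(s$abundance)))
    m[s$taxa, ] <- s$abundance
    m
  })
  mat <- do.call(cbind, unname(cols))
  tab_path <- file.path(out_dir, "taxa_table.tsv")
  utils::write.table(
    data.frame(taxon_id = all_taxa,
               format(mat, digits = 17, scientific = TRUE, trim = TRUE),
               check.names = FALSE),
    tab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  man <- do.call(rbind, unname(lapply(dataset$series, function(s) {
    data.frame(sample_id = s$samples$sample_id,
               patient_id = s$patient_id,
               collection_day = s$samples$collection_day,
               sample_type = s$samples$sample_type,
               stringsAsFactors = FALSE)
  })))
  man_path <- file.path(out_dir, "manifest.tsv")
  utils::write.table(man, man_path, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(tab_path, man_path)
  if (!is.null(dataset$metadata)) {
    clin_path <- file.path(out_dir, "clinical.tsv")
    utils::write.table(dataset$metadata, clin_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, clin_path)
  }
  invisible(paths)
}

#' Write pipeline results to TSV and JSON
#'
#' Writes whichever of the standard result tables are present in `results`:
#' `persistence.tsv`, `str_points.tsv`, `str_fits.tsv`,
#' `raup_crick_pairs.tsv`, `process_frequencies.tsv`, and always
#' `cohort_summary.json`.
#'
#' @param results Results bundle, e.g. from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c(persistence = "persistence", str_points = "str_points",
              str_fits = "str_fits", raup_crick_pairs = "raup_crick_pairs",
              process_frequencies = "process_frequencies")
  written <- character(0)
  for (nm in names(tables)) {
    df <- results[[nm]]
    if (is.null(df)) next
    path <- file.path(out_dir, paste0(tables[[nm]], ".tsv"))
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) format(v, digits = 15, trim = TRUE))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, path)
  }
  summary <- results$summary
  if (is.null(summary)) summary <- structure(list(), names = character(0))
  json_path <- file.path(out_dir, "cohort_summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(written, json_path))
}
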