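#' Run the full temporal-turnover analysis
#'
#' Orchestrates the whole analysis on a loaded cohort: inclusion filtering,
#' per-taxon persistence and the chronic/intermittent partition, per-patient
#' persistence-abundance fits, species-time relationships per colonizer group,
#' Raup-Crick process attribution against group-specific regional pools, and
#' cohort-level statistics.
#'
#' @param dataset A `cohort_dataset` (with metadata for the cohort-level
#'   statistics).
#' @param min_samples,min_duration_days Inclusion criteria, see
#'   [apply_inclusion_criteria()].
#' @param persistence_threshold_pct Leeds persistence threshold (default 50).
#' @param detection_min Detection threshold on relative abundance (default 0).
#' @param par_abundance_transform Predictor transform for PAR fits
#'   (default `"log10"`).
#' @param str_mode STR construction mode (default `"pairwise"`).
#' @param rc_iterations Monte-Carlo randomizations per sample pair
#'   (default 1000).
#' @param rc_threshold Raup-Crick classification threshold (default 0.95).
#' @param rc_weighting Null-assembly weighting, `"occurrence"` or `"uniform"`.
#' @param seed Master seed for all Monte-Carlo work (default 1).
#' @param groups Analysis groups (default microbiota, chronic, intermittent).
#' @param out_dir Optional directory; when given, results are written with
#'   [write_results()].
#' @param verbose Log per-stage progress via [message()].
#' @return Results bundle: data frames `persistence`, `par_fits`,
#'   `str_points`, `str_fits`, `raup_crick_pairs`, `process_frequencies`,
#'   `exclusions`, and a `summary` list (echoing the effective configuration).
#' @export
run_pipeline <- function(dataset,
                         min_samples = 6, min_duration_days = 731,
                         persistence_threshold_pct = 50,
                         detection_min = 0,
                         par_abundance_transform = c("log10", "identity"),
                         str_mode = c("pairwise", "window"),
                         rc_iterations = 1000, rc_threshold = 0.95,
                         rc_weighting = c("occurrence", "uniform"),
                         seed = 1,
                         groups = c("microbiota", "chronic", "intermittent"),
                         out_dir = NULL, verbose = TRUE) {
  par_abundance_transform <- match.arg(par_abundance_transform)
  str_mode <- match.arg(str_mode)
  rc_weighting <- match.arg(rc_weighting)
  stopifnot(inherits(dataset, "cohort_dataset"))
  say <- function(...) if (verbose) message(...)

  config <- list(min_samples = min_samples,
                 min_duration_days = min_duration_days,
                 persistence_threshold_pct = persistence_threshold_pct,
                 detection_min = detection_min,
                 par_abundance_transform = par_abundance_transform,
                 str_mode = str_mode, rc_iterations = rc_iterations,
                 rc_threshold = rc_threshold, rc_weighting = rc_weighting,
                 seed = seed, groups = groups)

  incl <- apply_inclusion_criteria(dataset, min_samples, min_duration_days)
  if (nrow(incl$exclusions))
    say("excluded ", nrow(incl$exclusions), " patient(s): ",
        paste(incl$exclusions$patient_id, incl$exclusions$reason,
              sep = " - ", collapse = "; "))
  dataset <- incl$dataset
  patients <- names(dataset$series)
  say("analysing ", length(patients), " patient(s)")

  records <- lapply(dataset$series, function(s)
    partition_leeds(taxon_persistence(s, detection_min),
                    persistence_threshold_pct))

  persistence <- do.call(rbind, c(unname(lapply(patients, function(pid)
    cbind(patient_id = pid,
          stats::setNames(records[[pid]],
                          c("taxon_id", "n_samples_detected", "n_samples_total",
                            "persistence_pct", "mean_rel_abund_detected",
                            "status")),
          stringsAsFactors = FALSE))),
    list(make.row.names = FALSE)))

  par_fits <- do.call(rbind, c(unname(lapply(patients, function(pid) {
    f <- tryCatch(fit_par(records[[pid]], par_abundance_transform),
                  error = function(e) {
                    say("patient ", pid, ": PAR fit skipped (",
                        conditionMessage(e), ")")
                    NULL
                  })
    if (is.null(f)) return(NULL)
    data.frame(patient_id = pid, slope = f$slope, intercept = f$intercept,
               r2 = f$r2, F = f$F, df1 = f$df[1], df2 = f$df[2], p = f$p,
               n_taxa = f$n_taxa, stringsAsFactors = FALSE)
  })), list(make.row.names = FALSE)))

  say("fitting species-time relationships (mode = ", str_mode, ")")
  str_points_all <- list()
  str_fits_all <- list()
  for (pid in patients) {
    res <- withCallingHandlers(
      str_for_groups(dataset$series[[pid]], records[[pid]], str_mode,
                     detection_min),
      warning = function(w) {
        say("STR: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    str_points_all[[pid]] <- res$points
    for (g in names(res$fits)) {
      f <- res$fits[[g]]
      if (is.null(f)) next
      str_fits_all[[paste(pid, g)]] <- data.frame(
        patient_id = pid, group = g, c = f$c, w = f$w, r2 = f$r2, F = f$F,
        df1 = f$df[1], df2 = f$df[2], p = f$p, n_points = f$n_points,
        stringsAsFactors = FALSE)
    }
  }
  str_points_df <- do.call(rbind, c(unname(str_points_all),
                                    list(make.row.names = FALSE)))
  str_points_df <- data.frame(
    patient_id = str_points_df$patient_id, group = str_points_df$group,
    window_start_sample = str_points_df$window_start,
    T_days = str_points_df$T_days, S_taxa = str_points_df$S_taxa,
    stringsAsFactors = FALSE)
  str_fits_df <- do.call(rbind, c(unname(str_fits_all),
                                  list(make.row.names = FALSE)))

  rc_pairs <- list()
  freqs <- list()
  for (g in groups) {
    say("Raup-Crick comparisons, group = ", g,
        " (", rc_iterations, " randomizations/pair, ", rc_weighting,
        " weighting)")
    pool <- build_regional_pool(dataset, g, rc_weighting,
                                persistence_threshold_pct, detection_min)
    for (pid in patients) {
      sub <- subset_series(dataset$series[[pid]], records[[pid]], g)
      if (length(sub$taxa) == 0) {
        say("patient ", pid, ", group ", g, ": no taxa, skipped")
        next
      }
      pairs <- withCallingHandlers(
        raup_crick_matrix(sub, pool, rc_iterations, seed, rc_threshold, g,
                          detection_min),
        message = function(m) {
          say(sub("\n$", "", conditionMessage(m)))
          invokeRestart("muffleMessage")
        })
      if (nrow(pairs) == 0) next
      rc_pairs[[paste(pid, g)]] <- pairs
      freqs[[paste(pid, g)]] <- process_frequencies(pairs)
    }
  }
  rc_pairs_df <- do.call(rbind, c(unname(rc_pairs), list(make.row.names = FALSE)))
  freqs_df <- do.call(rbind, c(unname(freqs), list(make.row.names = FALSE)))

  summary <- cohort_summary_stats(dataset, records, str_fits_df, freqs_df,
                                  config, incl$exclusions)

  results <- list(persistence = persistence, par_fits = par_fits,
                  str_points = str_points_df, str_fits = str_fits_df,
                  raup_crick_pairs = rc_pairs_df[, c("patient_id", "group",
                                                     "sample_a", "sample_b",
                                                     "s_rc", "process")],
                  process_frequencies = freqs_df,
                  exclusions = incl$exclusions,
                  summary = summary)
  if (!is.null(out_dir)) {
    paths <- write_results(results, out_dir)
    say("wrote ", length(paths), " file(s) to ", out_dir)
  }
  results
}

# Cohort-level statistics for the summary JSON: per-cohort means +/- SD of
# richness, turnover exponents, process frequencies and %FEV1, plus the
# standard tests (chronic vs intermittent w; paediatric vs adult %FEV1;
# exacerbations ~ %FEV1; process frequencies ~ %FEV1).
cohort_summary_stats <- function(dataset, records, str_fits_df, freqs_df,
                                 config, exclusions) {
  md <- dataset$metadata
  out <- list(config = config, n_patients = length(dataset$series),
              exclusions = exclusions)

  w_by_group <- split(str_fits_df$w, str_fits_df$group)
  out$w_mean_by_group <- lapply(w_by_group, function(v)
    list(mean = mean(v), sd = stats::sd(v), n = length(v)))
  if (all(c("chronic", "intermittent") %in% names(w_by_group)) &&
      all(lengths(w_by_group[c("chronic", "intermittent")]) >= 2)) {
    kw <- kruskal_wallis(w_by_group[c("chronic", "intermittent")])
    out$w_chronic_vs_intermittent <- list(H = kw$H, p = kw$p)
  }

  if (!is.null(md) && nrow(md) >= 2) {
    richness <- list(
      total = vapply(records, nrow, numeric(1)),
      chronic = vapply(records, function(r) sum(r$status == "chronic"),
                       numeric(1)),
      intermittent = vapply(records, function(r) sum(r$status == "intermittent"),
                            numeric(1)))
    out$richness <- lapply(richness, function(v)
      tryCatch(cohort_summaries(v, md), error = function(e) NULL))
    fev1 <- stats::setNames(md$mean_fev1, md$patient_id)
    out$fev1 <- cohort_summaries(fev1, md)
    by_cohort <- split(md$mean_fev1, md$cohort)
    if (length(by_cohort) == 2 && all(lengths(by_cohort) >= 2)) {
      kw <- kruskal_wallis(by_cohort)
      out$fev1_cohort_test <- list(H = kw$H, p = kw$p)
    }
    if (nrow(md) >= 3) {
      fit <- simple_ols(md$mean_fev1, md$exacerbations)
      out$exacerbations_vs_fev1 <- list(slope = fit$slope, r2 = fit$r2,
                                        F = fit$F, p = fit$p)
    }
    wm <- freqs_df[freqs_df$group == "microbiota", , drop = FALSE]
    out$process_vs_fev1 <- tryCatch({
      regs <- process_lungfunction_regressions(wm, md)
      lapply(regs, function(co) lapply(co, function(f)
        list(slope = f$slope, r2 = f$r2, F = f$F, p = f$p)))
    }, error = function(e) NULL)
  }

  if (!is.null(freqs_df)) {
    out$process_frequencies_by_group <- lapply(
      split(freqs_df, freqs_df$group), function(d)
        list(mean_pct_homogenizing = mean(d$pct_homogenizing),
             mean_pct_drift = mean(d$pct_drift),
             mean_pct_limitation = mean(d$pct_limitation),
             n_patients = nrow(d)))
  }
  out
}
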