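#' Per-taxon temporal persistence
#'
#' Persistence is the percentage of a patient's samples in which a taxon is
#' detected. Mean relative abundance is taken over only the samples in which
#' the taxon was detected.
#'
#' @param series A [taxa_time_series()].
#' @param detection_min Detection threshold on relative abundance (strict
#'   inequality; default 0).
#' @return Data frame with one row per detected taxon: `taxon_id`,
#'   `n_detected`, `n_total`, `persistence_pct`, `mean_abund_detected`, and
#'   `status` (`NA` until [partition_leeds()] is applied).
#' @export
taxon_persistence <- function(series, detection_min = 0) {
  stopifnot(inherits(series, "taxa_time_series"))
  pres <- presence_matrix(series, detection_min)
  n_total <- ncol(pres)
  if (n_total < 1) stop("series has no samples")
  n_det <- rowSums(pres)
  keep <- n_det > 0
  ab <- series$abundance
  mean_det <- vapply(which(keep), function(i) mean(ab[i, pres[i, ]]), numeric(1))
  data.frame(
    taxon_id = series$taxa[keep],
    n_detected = as.integer(n_det[keep]),
    n_total = as.integer(n_total),
    persistence_pct = 100 * n_det[keep] / n_total,
    mean_abund_detected = mean_det,
    status = NA_character_,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Partition taxa into chronic and intermittent colonizers
#'
#' Modified Leeds criteria: a taxon is a chronic colonizer of a patient if its
#' persistence is strictly greater than `threshold_pct`, otherwise
#' intermittent (so exactly 50% persistence is intermittent).
#'
#' @param records Persistence records from [taxon_persistence()].
#' @param threshold_pct Persistence threshold in percent, in (0, 100);
#'   default 50.
#' @return The records with `status` set to `"chronic"` or `"intermittent"`.
#' @export
partition_leeds <- function(records, threshold_pct = 50) {
  if (!is.numeric(threshold_pct) || length(threshold_pct) != 1 ||
      threshold_pct <= 0 || threshold_pct >= 100)
    stop("threshold_pct must lie in (0, 100)")
  records$status <- ifelse(records$persistence_pct > threshold_pct,
                           "chronic", "intermittent")
  records
}

#' Fit a persistence-abundance relationship (PAR)
#'
#' Ordinary least squares of persistence (%) on mean relative abundance when
#' detected, the temporal analogue of an occupancy-abundance relationship.
#' The abundance axis is log10-transformed by default.
#'
#' @param records Persistence records from [taxon_persistence()].
#' @param transform Abundance transform for the predictor: `"log10"`
#'   (default) or `"identity"`.
#' @return Object of class `par_fit`: `slope`, `intercept`, `r2`, `F`,
#'   `df` (length 2), `p`, `n_taxa`, `transform`.
#' @export
fit_par <- function(records, transform = c("log10", "identity")) {
  transform <- match.arg(transform)
  if (nrow(records) < 3) stop("need at least 3 taxa to fit a PAR")
  x <- switch(transform,
              log10 = log10(records$mean_abund_detected),
              identity = records$mean_abund_detected)
  y <- records$persistence_pct
  fit <- ols_fit(x, y)
  if (is.na(fit$slope)) stop("zero variance in abundance predictor")
  structure(c(fit, list(n_taxa = nrow(records), transform = transform)),
            class = "par_fit")
}

#' @export
print.par_fit <- function(x, ...) {
  cat(sprintf("PAR fit (n = %d taxa, %s abundance): slope = %.3g, R2 = %.3f, F(%d,%d) = %.3g, p = %.3g\n",
              x$n_taxa, x$transform, x$slope, x$r2, x$df[1], x$df[2], x$F, x$p))
  invisible(x)
}

#' Restrict a series to a colonization group
#'
#' Returns the series unchanged for `group = "microbiota"`; otherwise keeps
#' only the taxa labelled with the requested status. Abundances are not
#' renormalized: downstream analyses of the groups are presence/absence based.
#'
#' @param series A [taxa_time_series()].
#' @param records Persistence records with `status` set
#'   (see [partition_leeds()]).
#' @param group `"microbiota"`, `"chronic"`, or `"intermittent"`.
#' @return A `taxa_time_series` restricted to the group's taxa.
#' @export
subset_series <- function(series, records,
                          group = c("microbiota", "chronic", "intermittent")) {
  group <- match.arg(group)
  if (group == "microbiota") return(series)
  if (anyNA(records$status)) stop("records have unset status; run partition_leeds first")
  missing <- setdiff(series$taxa, records$taxon_id)
  if (length(missing))
    stop("records do not cover the series' taxa: ", paste(missing, collapse = ", "))
  keep <- records$taxon_id[records$status == group]
  out <- series
  out$abundance <- series$abundance[series$taxa %in% keep, , drop = FALSE]
  out$taxa <- rownames(out$abundance)
  out
}
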