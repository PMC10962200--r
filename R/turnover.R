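#' Species-time relationship points by the moving-window method
#'
#' In the default `pairwise` mode each adjacent pair of samples contributes
#' one point: `S` is the richness of the first sample plus the taxa newly
#' observed in the second (equivalently the size of the union of the two
#' presence sets), and `T` is the elapsed days between the two samples.
#' Because a taxon can immigrate and go locally extinct repeatedly, the same
#' taxon can count as "new" in several windows. The classical `window` mode
#' (all window lengths L = 2..N, `S` = union richness over the window,
#' `T` = elapsed days across it) is provided for sensitivity analysis.
#'
#' @param series A [taxa_time_series()].
#' @param mode `"pairwise"` (default) or `"window"`.
#' @param detection_min Detection threshold on relative abundance (default 0).
#' @return Data frame of points: `T_days`, `S_taxa`, `window_start` (sample
#'   index), `window_len`.
#' @export
str_points <- function(series, mode = c("pairwise", "window"),
                       detection_min = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "taxa_time_series"))
  n <- nrow(series$samples)
  if (n < 2) stop("need at least 2 samples to construct an STR")
  pres <- presence_matrix(series, detection_min)
  day <- series$samples$collection_day
  if (mode == "pairwise") {
    idx <- seq_len(n - 1)
    data.frame(
      T_days = day[idx + 1] - day[idx],
      S_taxa = vapply(idx, function(i) sum(pres[, i] | pres[, i + 1]), integer(1)),
      window_start = idx,
      window_len = 2L)
  } else {
    out <- list()
    for (L in 2:n) {
      for (i in seq_len(n - L + 1)) {
        cols <- i:(i + L - 1)
        out[[length(out) + 1]] <- data.frame(
          T_days = day[i + L - 1] - day[i],
          S_taxa = sum(rowSums(pres[, cols, drop = FALSE]) > 0),
          window_start = i,
          window_len = L)
      }
    }
    do.call(rbind, out)
  }
}

#' Fit the species-time power law S = c * T^w
#'
#' Ordinary least squares of log10 S on log10 T; the slope is the temporal
#' scaling exponent `w` (larger `w` = faster turnover) and `c = 10^intercept`.
#' Points with `S = 0` (possible for sparse group subsets) are dropped with a
#' warning before the log transform.
#'
#' @param points Data frame from [str_points()] (columns `T_days`, `S_taxa`).
#' @return Object of class `str_fit`: `c`, `w`, `r2`, `F`, `df`, `p`,
#'   `n_points`.
#' @export
fit_power_law <- function(points) {
  usable <- points$S_taxa > 0
  if (any(!usable))
    warning(sum(!usable), " STR point(s) with S = 0 dropped before log fit")
  points <- points[usable, , drop = FALSE]
  if (nrow(points) < 3) stop("need at least 3 usable points for a power-law fit")
  if (any(points$T_days <= 0)) stop("nonpositive elapsed time in STR points")
  x <- log10(points$T_days)
  y <- log10(points$S_taxa)
  fit <- ols_fit(x, y)
  if (is.na(fit$slope)) stop("zero variance in log10 T; cannot fit power law")
  structure(list(c = 10^fit$intercept, w = fit$slope, r2 = fit$r2,
                 F = fit$F, df = fit$df, p = fit$p, n_points = nrow(points)),
            class = "str_fit")
}

#' @export
print.str_fit <- function(x, ...) {
  cat(sprintf("STR power-law fit: S = %.3g * T^%.4f (n = %d, R2 = %.3f, p = %.3g)\n",
              x$c, x$w, x$n_points, x$r2, x$p))
  invisible(x)
}

#' Species-time relationships for the microbiota and both colonizer groups
#'
#' Applies [subset_series()], [str_points()] and [fit_power_law()] for the
#' whole microbiota and the chronic and intermittent groups. Presence is
#' evaluated on the subset matrices.
#'
#' @param series A [taxa_time_series()].
#' @param records Persistence records with `status` set.
#' @param mode STR construction mode, see [str_points()].
#' @param detection_min Detection threshold (default 0).
#' @return List with `points` (data frame with a `group` column) and `fits`
#'   (named list of `str_fit`, entries `NULL` with a warning if a group has
#'   too few usable points).
#' @export
str_for_groups <- function(series, records, mode = c("pairwise", "window"),
                           detection_min = 0) {
  mode <- match.arg(mode)
  groups <- c("microbiota", "chronic", "intermittent")
  pts <- list()
  fits <- stats::setNames(vector("list", 3), groups)
  for (g in groups) {
    sub <- subset_series(series, records, g)
    if (length(sub$taxa) == 0) {
      warning("patient ", series$patient_id, ": no taxa in group ", g)
      next
    }
    p <- str_points(sub, mode, detection_min)
    p <- cbind(patient_id = series$patient_id, group = g, p,
               stringsAsFactors = FALSE)
    pts[[g]] <- p
    fits[[g]] <- tryCatch(fit_power_law(p), error = function(e) {
      warning("patient ", series$patient_id, ", group ", g, ": ",
              conditionMessage(e))
      NULL
    })
  }
  list(points = do.call(rbind, c(pts, list(make.row.names = FALSE))),
       fits = fits)
}
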