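#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference distribution
#' (k - 1 degrees of freedom), via [stats::kruskal.test()].
#'
#' @param groups List of two or more numeric vectors.
#' @return Object of class `kruskal_result`: `H`, `df`, `p`, `group_ns`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  ns <- lengths(groups)
  if (any(ns < 2)) stop("every group needs at least 2 values")
  if (length(unique(unlist(groups))) == 1) {
    # fully tied data: rank variance is zero, take H = 0 by continuity
    return(structure(list(H = 0, df = length(groups) - 1L, p = 1,
                          group_ns = ns), class = "kruskal_result"))
  }
  kt <- stats::kruskal.test(groups)
  structure(list(H = unname(kt$statistic), df = unname(kt$parameter),
                 p = kt$p.value, group_ns = ns),
            class = "kruskal_result")
}

#' @export
print.kruskal_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g (n = %s)\n",
              x$H, x$df, x$p, paste(x$group_ns, collapse = ", ")))
  invisible(x)
}

#' Dunn's post-hoc test on pooled ranks
#'
#' Pairwise z statistics on the pooled-rank means with tie correction,
#' following Dunn (1964):
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - C_ties) (1/n_i + 1/n_j))`
#' with `C_ties = sum(t^3 - t) / (12 (N - 1))`. Two-sided normal p values,
#' adjusted for the number of comparisons.
#'
#' @param groups Named (or unnamed) list of numeric vectors.
#' @param adjustment `"bonferroni"` (default), `"holm"`, or `"none"`.
#' @return Data frame with one row per pair: `group_a`, `group_b`, `z`, `p`,
#'   `p_adjusted`.
#' @export
dunn_posthoc <- function(groups, adjustment = c("bonferroni", "holm", "none")) {
  adjustment <- match.arg(adjustment)
  if (length(groups) < 2) stop("need at least two groups")
  if (any(lengths(groups) == 0)) stop("empty group")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  ns <- lengths(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), ns)
  r <- rank(x)
  N <- length(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  combos <- utils::combn(names(groups), 2)
  z <- vapply(seq_len(ncol(combos)), function(k) {
    i <- combos[1, k]; j <- combos[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[[i]] + 1 / ns[[j]]))
    if (se == 0) 0 else (rbar[[i]] - rbar[[j]]) / se
  }, numeric(1))
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group_a = combos[1, ], group_b = combos[2, ], z = z, p = p,
             p_adjusted = stats::p.adjust(p, method = adjustment),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simple ordinary least squares regression
#'
#' OLS of `y` on `x`, reporting `r2`, `F = r2/(1-r2) * (n-2)` on (1, n-2)
#' degrees of freedom, and its p value.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return Object of class `ols_result`: `slope`, `intercept`, `r2`, `F`,
#'   `df`, `p`, `n`.
#' @export
simple_ols <- function(x, y) {
  fit <- ols_fit(x, y)
  if (is.na(fit$slope)) stop("zero variance in predictor")
  structure(fit, class = "ols_result")
}

#' @export
print.ols_result <- function(x, ...) {
  cat(sprintf("OLS: slope = %.4g, R2 = %.3f, F(%d,%d) = %.4g, p = %.4g\n",
              x$slope, x$r2, x$df[1], x$df[2], x$F, x$p))
  invisible(x)
}

#' Per-cohort mean and standard deviation
#'
#' @param values Numeric vector named by patient id.
#' @param metadata Clinical table with `patient_id` and `cohort`.
#' @return Data frame per cohort label: `label`, `n`, `mean`, `sd` (sample SD,
#'   n-1 denominator; 0 with a warning for single-patient groups),
#'   `sd_undefined` flag.
#' @export
cohort_summaries <- function(values, metadata) {
  ids <- names(values)
  if (is.null(ids)) stop("values must be named by patient_id")
  unknown <- setdiff(ids, metadata$patient_id)
  if (length(unknown)) stop("unknown patient(s): ", paste(unknown, collapse = ", "))
  cohort <- metadata$cohort[match(ids, metadata$patient_id)]
  out <- lapply(split(as.numeric(values), cohort), function(v) {
    if (length(v) == 1) {
      warning("single-patient group: SD undefined, reported as 0")
      c(n = 1, mean = v, sd = 0, sd_undefined = 1)
    } else c(n = length(v), mean = mean(v), sd = stats::sd(v), sd_undefined = 0)
  })
  df <- as.data.frame(do.call(rbind, out))
  data.frame(label = names(out), n = as.integer(df$n), mean = df$mean,
             sd = df$sd, sd_undefined = df$sd_undefined == 1,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Regressions of process frequencies on lung function
#'
#' For each requested cohort, OLS of the whole-microbiota percentage frequency
#' of homogenizing dispersal on mean %FEV1, and of drift on mean %FEV1.
#'
#' @param freqs Data frame of whole-microbiota process frequencies (one row
#'   per patient: `patient_id`, `pct_homogenizing`, `pct_drift`).
#' @param metadata Clinical table (`patient_id`, `cohort`, `mean_fev1`).
#' @param cohorts Cohort labels to fit (default both).
#' @return Named list (per cohort) of lists with `homogenizing` and `drift`
#'   [simple_ols()] fits.
#' @export
process_lungfunction_regressions <- function(freqs, metadata,
                                             cohorts = c("paediatric", "adult")) {
  if (anyDuplicated(freqs$patient_id))
    stop("freqs must have one whole-microbiota row per patient")
  m <- merge(freqs, metadata[, c("patient_id", "cohort", "mean_fev1")],
             by = "patient_id")
  out <- list()
  for (co in cohorts) {
    sub <- m[m$cohort == co, , drop = FALSE]
    if (nrow(sub) < 3) stop("fewer than 3 patients in cohort ", co)
    out[[co]] <- list(
      homogenizing = simple_ols(sub$mean_fev1, sub$pct_homogenizing),
      drift = simple_ols(sub$mean_fev1, sub$pct_drift))
  }
  out
}
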