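# Build a taxa_time_series directly from a matrix and collection days.
make_series <- function(mat, days, patient_id = "P1", normalize = TRUE) {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("t", seq_len(nrow(mat)))
  if (is.null(colnames(mat)))
    colnames(mat) <- paste0(patient_id, "_s", seq_len(ncol(mat)))
  taxa_time_series(patient_id, mat,
                   data.frame(sample_id = colnames(mat),
                              collection_day = days,
                              sample_type = "sputum",
                              stringsAsFactors = FALSE),
                   normalize = normalize)
}

# Series from presence sets (named list of taxon-id vectors), one per day.
series_from_sets <- function(sets, days, patient_id = "P1") {
  taxa <- sort(unique(unlist(sets)))
  mat <- sapply(sets, function(s) as.numeric(taxa %in% s))
  rownames(mat) <- taxa
  colnames(mat) <- paste0(patient_id, "_s", seq_along(sets))
  make_series(mat, days, patient_id)
}

# Two-patient toy cohort on disk: 4 taxa x 5 samples.
# P1 (s1-s3) touches all 4 taxa; P2 (s4, s5) never sees taxon A.
write_toy_cohort_files <- function(dir = tempfile("toycohort")) {
  dir.create(dir)
  tab <- data.frame(
    taxon_id = c("A", "B", "C", "D"),
    s1 = c(10, 0, 30, 60),
    s2 = c(5, 5, 0, 90),
    s3 = c(0, 10, 10, 80),
    s4 = c(0, 2, 0, 8),
    s5 = c(0, 0, 5, 5))
  man <- data.frame(sample_id = paste0("s", 1:5),
                    patient_id = c("P1", "P1", "P1", "P2", "P2"),
                    collection_day = c(0, 30, 60, 0, 40),
                    sample_type = c("sputum", "sputum", "cough_swab",
                                    "sputum", "sputum"))
  utils::write.table(tab, file.path(dir, "taxa_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dir
}

# Independent normal-equations OLS oracle (closed form, no lm).
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  sst <- sum((y - mean(y))^2)
  sse <- sum((y - intercept - slope * x)^2)
  r2 <- 1 - sse / sst
  F <- r2 / (1 - r2) * (n - 2)
  list(slope = slope, intercept = intercept, r2 = r2, F = F,
       p = stats::pf(F, 1, n - 2, lower.tail = FALSE))
}

# Independent tie-corrected Kruskal-Wallis oracle from the rank formula.
kw_oracle <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  N <- length(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Independent hypergeometric Raup-Crick oracle via binomial coefficients.
hyper_src_oracle <- function(N, n_a, n_b, shared) {
  ks <- max(0, n_a + n_b - N):min(n_a, n_b)
  pk <- choose(n_a, ks) * choose(N - n_a, n_b - ks) / choose(N, n_b)
  p <- sum(pk[ks < shared]) + 0.5 * pk[ks == shared]
  2 * p - 1
}

# Brute-force union richness over a sample window.
union_richness <- function(series, cols) {
  pres <- series$abundance > 0
  sum(rowSums(pres[, cols, drop = FALSE]) > 0)
}
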