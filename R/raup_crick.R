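#' Construct a regional species pool
#'
#' @param taxa Character vector of taxon identifiers.
#' @param occurrence Integer vector of per-taxon occurrence counts (number of
#'   samples in which the taxon was detected); required for
#'   `weighting = "occurrence"`.
#' @param weighting `"occurrence"` (null-community assembly probabilities
#'   proportional to how often each taxon occurs) or `"uniform"`.
#' @return Object of class `species_pool` with `taxa`, `occurrence`,
#'   `weights` (summing to 1) and `weighting`.
#' @export
species_pool <- function(taxa, occurrence = NULL,
                         weighting = c("occurrence", "uniform")) {
  weighting <- match.arg(weighting)
  taxa <- as.character(taxa)
  if (length(taxa) == 0) stop("empty species pool")
  if (anyDuplicated(taxa)) stop("duplicate taxa in pool")
  if (is.null(occurrence)) {
    if (weighting == "occurrence")
      stop("occurrence counts required for occurrence weighting")
    occurrence <- rep(1L, length(taxa))
  }
  if (length(occurrence) != length(taxa) || any(occurrence < 1))
    stop("every pool taxon needs occurrence >= 1")
  w <- switch(weighting,
              occurrence = occurrence / sum(occurrence),
              uniform = rep(1 / length(taxa), length(taxa)))
  structure(list(taxa = taxa, occurrence = as.integer(occurrence),
                 weights = w, weighting = weighting),
            class = "species_pool")
}

#' @export
print.species_pool <- function(x, ...) {
  cat("species_pool:", length(x$taxa), "taxa,", x$weighting, "weighting\n")
  invisible(x)
}

#' Build the regional species pool from a cohort
#'
#' The regional pool is the union of all taxa detected in any sample of any
#' patient, with occurrence counts tallied over all samples. For
#' `group = "chronic"` or `"intermittent"` the pool is restricted to taxa
#' carrying that colonization status in at least one patient.
#'
#' @param dataset A `cohort_dataset`.
#' @param group `"microbiota"`, `"chronic"`, or `"intermittent"`.
#' @param weighting See [species_pool()].
#' @param threshold_pct Persistence threshold used to assign status when
#'   `group != "microbiota"` (default 50).
#' @param detection_min Detection threshold on relative abundance (default 0).
#' @return A `species_pool`.
#' @export
build_regional_pool <- function(dataset,
                                group = c("microbiota", "chronic", "intermittent"),
                                weighting = c("occurrence", "uniform"),
                                threshold_pct = 50, detection_min = 0) {
  group <- match.arg(group)
  weighting <- match.arg(weighting)
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (length(dataset$series) == 0) stop("empty cohort")
  occ <- new.env(parent = emptyenv())
  status_taxa <- character(0)
  for (s in dataset$series) {
    pres <- presence_matrix(s, detection_min)
    det <- rowSums(pres)
    for (i in which(det > 0)) {
      t <- s$taxa[i]
      occ[[t]] <- (if (is.null(occ[[t]])) 0L else occ[[t]]) + as.integer(det[i])
    }
    if (group != "microbiota") {
      rec <- partition_leeds(taxon_persistence(s, detection_min), threshold_pct)
      status_taxa <- union(status_taxa, rec$taxon_id[rec$status == group])
    }
  }
  taxa <- sort(ls(occ))
  if (group != "microbiota") taxa <- intersect(taxa, sort(status_taxa))
  if (length(taxa) == 0) stop("no taxa in the regional pool for group ", group)
  occurrence <- vapply(taxa, function(t) occ[[t]], integer(1))
  species_pool(taxa, occurrence, weighting)
}

#' Raup-Crick similarity for one pair of samples
#'
#' Compares the observed number of shared taxa between two presence sets to a
#' Monte-Carlo null in which both communities are assembled at their observed
#' richness by weighted sampling without replacement from the regional pool.
#' With `p` the null probability of fewer shared taxa than observed (ties
#' counted half), the index is `s_rc = 2p - 1`, oriented as a similarity:
#' +1 means far more similar than expected by chance, -1 far less.
#'
#' @param presence_a,presence_b Character vectors of detected taxa (subsets of
#'   the pool).
#' @param pool A [species_pool()].
#' @param iterations Number of Monte-Carlo randomizations (default 1000).
#' @param seed Optional integer seed for this comparison; the caller's RNG
#'   state is preserved.
#' @param threshold Classification threshold on `|s_rc|` (default 0.95).
#' @return Object of class `raup_crick_pair`: `n_a`, `n_b`, `shared_obs`,
#'   `p`, `s_rc`, `process`.
#' @export
raup_crick_pair <- function(presence_a, presence_b, pool, iterations = 1000,
                            seed = NULL, threshold = 0.95) {
  stopifnot(inherits(pool, "species_pool"))
  presence_a <- unique(as.character(presence_a))
  presence_b <- unique(as.character(presence_b))
  out_a <- setdiff(presence_a, pool$taxa)
  out_b <- setdiff(presence_b, pool$taxa)
  if (length(out_a) || length(out_b))
    stop("presence sets contain taxa outside the pool: ",
         paste(c(out_a, out_b), collapse = ", "))
  n_a <- length(presence_a)
  n_b <- length(presence_b)
  if (n_a < 1 || n_b < 1) stop("presence sets must be nonempty")
  shared_obs <- length(intersect(presence_a, presence_b))
  # canonical draw order, so s_rc(a, b) == s_rc(b, a) exactly under a seed
  key_a <- paste(sort(presence_a), collapse = ",")
  key_b <- paste(sort(presence_b), collapse = ",")
  d <- if (n_a > n_b || (n_a == n_b && key_a > key_b)) c(n_b, n_a) else c(n_a, n_b)
  counts <- if (is.null(seed)) {
    rc_null_counts(pool$weights, d[1], d[2], shared_obs, iterations)
  } else {
    with_seed(seed, rc_null_counts(pool$weights, d[1], d[2], shared_obs, iterations))
  }
  p <- (counts[1] + 0.5 * counts[2]) / iterations
  s_rc <- 2 * p - 1
  structure(list(n_a = n_a, n_b = n_b, shared_obs = shared_obs,
                 p = p, s_rc = s_rc,
                 process = classify_process(s_rc, threshold)),
            class = "raup_crick_pair")
}

#' Exact null distribution of the Raup-Crick index
#'
#' Independent oracle for [raup_crick_pair()]. For uniform pools the null
#' shared-taxa count is hypergeometric and the index has a closed form; for
#' weighted pools of at most 12 taxa the successive-sampling distribution of
#' both communities is enumerated exhaustively. Tie-splitting and rescaling
#' match the Monte-Carlo estimator.
#'
#' @param pool A [species_pool()].
#' @param n_a,n_b Community richnesses.
#' @param shared_obs Observed shared-taxa count.
#' @return List with the exact `p`, `s_rc`, and the null `distribution`
#'   (named probability vector over shared counts).
#' @export
exact_null_srcs <- function(pool, n_a, n_b, shared_obs) {
  stopifnot(inherits(pool, "species_pool"))
  N <- length(pool$taxa)
  if (n_a < 1 || n_b < 1 || n_a > N || n_b > N)
    stop("community sizes must lie in [1, pool size]")
  lo <- max(0L, n_a + n_b - N)
  hi <- min(n_a, n_b)
  if (shared_obs < lo || shared_obs > hi)
    stop("shared_obs = ", shared_obs, " impossible for pool ", N,
         " with richnesses ", n_a, ", ", n_b)
  uniform <- diff(range(pool$weights)) < 1e-12
  ks <- lo:hi
  if (uniform) {
    dist <- stats::dhyper(ks, n_a, N - n_a, n_b)
  } else {
    if (N > 12) stop("exhaustive enumeration refused for weighted pools > 12 taxa")
    dist <- weighted_shared_distribution(pool$weights, n_a, n_b)[ks + 1]
  }
  names(dist) <- ks
  p <- sum(dist[ks < shared_obs]) + 0.5 * dist[as.character(shared_obs)]
  list(p = unname(p), s_rc = unname(2 * p - 1), distribution = dist)
}

# Exact distribution of |A intersect B| when A and B are independent
# successive weighted draws (sizes n_a, n_b) from a pool of N <= 12 taxa.
weighted_shared_distribution <- function(w, n_a, n_b) {
  N <- length(w)
  masks_a <- subset_masks(N, n_a)
  masks_b <- if (n_b == n_a) masks_a else subset_masks(N, n_b)
  pa <- vapply(masks_a, function(m) successive_set_prob(w, m), numeric(1))
  pb <- if (n_b == n_a) pa else
    vapply(masks_b, function(m) successive_set_prob(w, m), numeric(1))
  popcount <- vapply(0:(2^N - 1), function(m) sum(bitwAnd(m, 2^(0:(N - 1))) > 0),
                     integer(1))
  dist <- numeric(min(n_a, n_b) + 1)
  for (i in seq_along(masks_a)) {
    k <- popcount[bitwAnd(masks_a[i], masks_b) + 1L]
    contrib <- pa[i] * pb
    for (kk in unique(k)) dist[kk + 1] <- dist[kk + 1] + sum(contrib[k == kk])
  }
  dist
}

subset_masks <- function(N, n) {
  combos <- utils::combn(N, n)
  as.integer(colSums(matrix(2^(combos - 1), nrow = n)))
}

# P(first |S| successive weighted draws are exactly the set S), by dynamic
# programming over subsets of S: g(T) = sum_i g(T-i) * w_i / (W - w(T-i)).
successive_set_prob <- function(w, mask) {
  members <- which(bitwAnd(mask, 2^(seq_along(w) - 1)) > 0)
  k <- length(members)
  W <- sum(w)
  wm <- w[members]
  g <- numeric(2^k)
  g[1] <- 1
  wT <- vapply(0:(2^k - 1), function(m) sum(wm[bitwAnd(m, 2^(0:(k - 1))) > 0]),
               numeric(1))
  for (m in 1:(2^k - 1)) {
    tot <- 0
    for (j in seq_len(k)) {
      bit <- 2^(j - 1)
      if (bitwAnd(m, bit) > 0) {
        prev <- m - bit
        tot <- tot + g[prev + 1] * wm[j] / (W - wT[prev + 1])
      }
    }
    g[m + 1] <- tot
  }
  g[2^k]
}

#' All pairwise Raup-Crick comparisons within a patient
#'
#' Computes `s_rc` for every unordered pair of the patient's samples. Each
#' pair gets its own RNG substream derived from the master seed, the patient,
#' the group label, and the (sorted) sample identifiers, so results do not
#' depend on evaluation order and are symmetric in the pair.
#'
#' @param series A [taxa_time_series()] (possibly a group subset from
#'   [subset_series()]).
#' @param pool A [species_pool()].
#' @param iterations Monte-Carlo randomizations per pair (default 1000).
#' @param seed Master seed (integer).
#' @param threshold Classification threshold (default 0.95).
#' @param group Group label recorded in the output and mixed into the per-pair
#'   seeds.
#' @param detection_min Detection threshold (default 0).
#' @return Data frame with one row per usable pair: `patient_id`, `group`,
#'   `sample_a`, `sample_b`, `n_a`, `n_b`, `shared_obs`, `s_rc`, `process`.
#'   Samples with no detected taxa in the group are skipped with a message.
#' @export
raup_crick_matrix <- function(series, pool, iterations = 1000, seed = 1,
                              threshold = 0.95, group = "microbiota",
                              detection_min = 0) {
  stopifnot(inherits(series, "taxa_time_series"))
  pres <- presence_matrix(series, detection_min)
  sets <- lapply(seq_len(ncol(pres)), function(j) series$taxa[pres[, j]])
  names(sets) <- series$samples$sample_id
  empty <- lengths(sets) == 0
  if (any(empty)) {
    message("patient ", series$patient_id, ", group ", group, ": skipping ",
            sum(empty), " sample(s) with no detected taxa: ",
            paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  ids <- names(sets)
  if (length(ids) < 2)
    return(data.frame(patient_id = character(0), group = character(0),
                      sample_a = character(0), sample_b = character(0),
                      n_a = integer(0), n_b = integer(0),
                      shared_obs = integer(0), s_rc = numeric(0),
                      process = character(0), stringsAsFactors = FALSE))
  combos <- utils::combn(length(ids), 2)
  rows <- lapply(seq_len(ncol(combos)), function(k) {
    a <- ids[combos[1, k]]; b <- ids[combos[2, k]]
    ab <- sort(c(a, b))
    pair_seed <- hash_seed(series$patient_id, group, ab[1], ab[2],
                           master_seed = seed)
    rc <- raup_crick_pair(sets[[a]], sets[[b]], pool, iterations,
                          seed = pair_seed, threshold = threshold)
    data.frame(patient_id = series$patient_id, group = group,
               sample_a = a, sample_b = b, n_a = rc$n_a, n_b = rc$n_b,
               shared_obs = rc$shared_obs, s_rc = rc$s_rc,
               process = rc$process, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Classify an ecological process from a Raup-Crick index
#'
#' `s_rc >= threshold` indicates communities significantly more similar than
#' chance (homogenizing dispersal); `s_rc <= -threshold` significantly less
#' similar (dispersal limitation); values in between are consistent with
#' ecological drift. Boundaries are inclusive.
#'
#' @param s_rc Numeric vector of indices in \[-1, 1\].
#' @param threshold Classification threshold (default 0.95).
#' @return Character vector: `"homogenizing_dispersal"`, `"drift"`, or
#'   `"dispersal_limitation"`.
#' @export
classify_process <- function(s_rc, threshold = 0.95) {
  if (any(!is.finite(s_rc)) || any(s_rc < -1 - 1e-12) || any(s_rc > 1 + 1e-12))
    stop("s_rc values must lie in [-1, 1]")
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  ifelse(s_rc >= threshold, "homogenizing_dispersal",
         ifelse(s_rc <= -threshold, "dispersal_limitation", "drift"))
}

#' Percentage frequencies of the inferred processes
#'
#' @param pairs Data frame from [raup_crick_matrix()] (needs a `process`
#'   column; `patient_id`/`group` carried through when present and unique).
#' @return One-row data frame: `patient_id`, `group`, `pct_homogenizing`,
#'   `pct_drift`, `pct_limitation`, `n_pairs`. Percentages sum to 100.
#' @export
process_frequencies <- function(pairs) {
  n <- nrow(pairs)
  if (is.null(n) || n == 0) stop("no pairs to summarize")
  lab <- function(col) {
    v <- unique(pairs[[col]])
    if (length(v) == 1) v else NA_character_
  }
  data.frame(
    patient_id = lab("patient_id"),
    group = lab("group"),
    pct_homogenizing = 100 * sum(pairs$process == "homogenizing_dispersal") / n,
    pct_drift = 100 * sum(pairs$process == "drift") / n,
    pct_limitation = 100 * sum(pairs$process == "dispersal_limitation") / n,
    n_pairs = as.integer(n),
    stringsAsFactors = FALSE)
}
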