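#' Configuration for the synthetic-cohort generator
#'
#' The generator emulates the statistical structure of a longitudinal CF-lung
#' cohort: 6-20 samples per patient spread over 785-1166 days; a resident
#' taxon class (high detection probability, high abundance) and a transient
#' class (low detection probability, rare), coupled so that
#' persistence-abundance relationships are positive; cross-patient sharing of
#' common taxa through a global commonness gradient, which gives the
#' occurrence-weighted regional pool the skew real cohorts have; and clinical
#' covariates in which exacerbation counts fall with lung function.
#'
#' Two between-sample overlap regimes are available. In the `homogenizing`
#' regime each patient's detections come from a fixed template community,
#' re-expressed at every visit with a small flip noise: samples are far more
#' similar than a regional-pool null expects. In the `drift` regime each
#' taxon's presence follows a stationary two-state Markov chain with the
#' configured detection probability as its stationary mean and correlation
#' time `drift_tau_days`: for sampling gaps much longer than the correlation
#' time this is independent assembly from the patient's pool, while short
#' gaps retain the temporal autocorrelation that gives species-time
#' relationships a positive exponent.
#'
#' @param n_patients Patients per cohort (default 15, as in the study design).
#' @param global_pool_size Taxa in the global pool (default 600).
#' @param per_patient_pool Integer range of per-patient pool sizes
#'   (default c(120, 260)).
#' @param resident_fraction Fraction of a patient's taxa designated resident
#'   (default 0.12).
#' @param resident_detection_prob Range of resident per-sample detection
#'   probabilities (default c(0.70, 0.98); entirely above 0.5 so residents are
#'   expected to classify chronic).
#' @param transient_detection_prob Range for transients (default c(0.02, 0.30)).
#' @param abundance_coupling Slope linking latent log10 mean abundance to the
#'   logit of detection probability (default 0.6, positive so the PAR is
#'   positive by construction).
#' @param abundance_noise_sd SD of per-patient taxon log10-abundance noise
#'   around the coupling line (default 0.35).
#' @param lognormal_sigma sdlog of the per-detection lognormal abundance
#'   fluctuation (default 1).
#' @param n_samples Integer range of samples per patient (default c(6, 20)).
#' @param duration_days Integer range of the last collection day
#'   (default c(785, 1166)).
#' @param regime `"drift"` (default) or `"homogenizing"`.
#' @param flip_noise Per-sample, per-taxon probability that the homogenizing
#'   template state is flipped (default 0.03).
#' @param drift_tau_days Correlation time of the drift-regime presence process
#'   in days (default 90, about one inter-visit gap).
#' @param n_core Size of the global candidate-resident core (default 40).
#'   Residents are nested: a patient with `k` residents carries core ranks
#'   1..k, so low ranks are residents of every patient, like canonical airway
#'   taxa, and the occurrence-weighted regional null reassembles them at
#'   close to their detection probability.
#' @param transient_decay E-folding (in ranks) of transient pool-membership
#'   weight (default 200).
#' @param transient_p_decay E-folding (in ranks) of transient detection
#'   probability down the commonness gradient (default 40): only globally
#'   common transients are detected often, the long tail is rare everywhere.
#' @param fev1 List of per-cohort `c(mean, sd)` for %FEV1 (defaults: the
#'   study's cohort summaries, paediatric 90.5 +/- 14.5, adult 75.9 +/- 18.9).
#' @param exacerbation_link Coefficient of %FEV1 in the log exacerbation rate
#'   (default -0.03; negative reproduces the inverse relationship).
#' @param exacerbation_intercept Intercept of the log exacerbation rate
#'   (default 3.2, about 2.6 expected exacerbations at %FEV1 = 85).
#' @param h_base Optional baseline mixing weight in (0, 1) between template
#'   (homogenizing) and Markov (drift) presence per taxon-sample; `NULL`
#'   (default) uses the pure regime.
#' @param h_fev1_coupling Slope of the patient mixing weight on standardized
#'   %FEV1 (logit scale; default 0, no coupling). Negative values make worse
#'   lung function more homogenizing, for regression-recovery experiments.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 15,
                             global_pool_size = 600,
                             per_patient_pool = c(120, 260),
                             resident_fraction = 0.12,
                             resident_detection_prob = c(0.70, 0.98),
                             transient_detection_prob = c(0.02, 0.30),
                             abundance_coupling = 0.6,
                             abundance_noise_sd = 0.35,
                             lognormal_sigma = 1,
                             n_samples = c(6, 20),
                             duration_days = c(785, 1166),
                             regime = c("drift", "homogenizing"),
                             flip_noise = 0.03,
                             drift_tau_days = 90,
                             n_core = 40,
                             transient_decay = 200,
                             transient_p_decay = 40,
                             fev1 = list(paediatric = c(mean = 90.5, sd = 14.5),
                                         adult = c(mean = 75.9, sd = 18.9)),
                             exacerbation_link = -0.03,
                             exacerbation_intercept = 3.2,
                             h_base = NULL,
                             h_fev1_coupling = 0) {
  regime <- match.arg(regime)
  chk_range <- function(r, nm, lo = 0, hi = 1) {
    if (length(r) != 2 || r[1] > r[2] || r[1] <= lo || r[2] >= hi)
      stop(nm, " must be an increasing range inside (", lo, ", ", hi, ")")
  }
  chk_range(resident_detection_prob, "resident_detection_prob")
  chk_range(transient_detection_prob, "transient_detection_prob")
  if (resident_detection_prob[1] <= 0.5)
    stop("resident_detection_prob must lie entirely above 0.5")
  if (any(per_patient_pool < 1) || per_patient_pool[1] > per_patient_pool[2])
    stop("invalid per_patient_pool range")
  if (any(duration_days <= 0) || duration_days[1] > duration_days[2])
    stop("invalid duration_days range")
  if (any(n_samples < 2) || n_samples[1] > n_samples[2])
    stop("invalid n_samples range")
  if (n_samples[2] - 1 > duration_days[1])
    stop("n_samples can exceed the number of distinct sampling days")
  if (resident_fraction <= 0 || resident_fraction >= 1)
    stop("resident_fraction must lie in (0, 1)")
  max_res <- round(resident_fraction * per_patient_pool[2])
  if (max_res > n_core)
    stop("resident_fraction * per_patient_pool exceeds n_core")
  if (per_patient_pool[2] - 1 > global_pool_size - n_core)
    stop("per-patient pool exceeds the transient pool")
  if (flip_noise < 0 || flip_noise >= 0.5) stop("flip_noise must lie in [0, 0.5)")
  if (drift_tau_days <= 0) stop("drift_tau_days must be positive")
  if (!is.null(h_base) && (h_base <= 0 || h_base >= 1))
    stop("h_base must lie in (0, 1)")
  structure(list(
    n_patients = n_patients, global_pool_size = global_pool_size,
    per_patient_pool = per_patient_pool, resident_fraction = resident_fraction,
    resident_detection_prob = resident_detection_prob,
    transient_detection_prob = transient_detection_prob,
    abundance_coupling = abundance_coupling,
    abundance_noise_sd = abundance_noise_sd,
    lognormal_sigma = lognormal_sigma, n_samples = n_samples,
    duration_days = duration_days, regime = regime, flip_noise = flip_noise,
    drift_tau_days = drift_tau_days, n_core = n_core,
    transient_decay = transient_decay, transient_p_decay = transient_p_decay,
    fev1 = fev1,
    exacerbation_link = exacerbation_link,
    exacerbation_intercept = exacerbation_intercept,
    h_base = h_base, h_fev1_coupling = h_fev1_coupling),
    class = "generator_config")
}

# Deterministic global taxon attributes implied by a config: ids, the
# candidate-resident core with detection probability declining across ranks,
# and transients whose pool-membership weight and detection probability decay
# together down the commonness gradient.
global_pool_attributes <- function(config) {
  G <- config$global_pool_size
  nc <- config$n_core
  ids <- sprintf("t%04d", seq_len(G))
  rd <- config$resident_detection_prob
  td <- config$transient_detection_prob
  core_p <- rd[2] - (rd[2] - rd[1]) * (seq_len(nc) - 1) / (nc - 1)
  tr_rank <- seq_len(G - nc)
  tr_common <- exp(-tr_rank / config$transient_decay)
  tr_p <- td[1] + (td[2] - td[1]) * exp(-tr_rank / config$transient_p_decay)
  list(ids = ids,
       core_ids = ids[seq_len(nc)], core_p = core_p,
       transient_ids = ids[(nc + 1):G], transient_p = tr_p,
       transient_w = tr_common)
}

#' Generate one patient's longitudinal taxa series
#'
#' @param config A [generator_config()].
#' @param patient_id Patient identifier.
#' @param seed Integer seed (the series is fully reproducible from it).
#' @param h Optional mixing weight in \[0, 1\] between the homogenizing
#'   template process (1) and the drift Markov process (0), overriding the
#'   regime; used by [generate_cohort()] for lung-function coupling.
#' @return A [taxa_time_series()].
#' @export
generate_patient_series <- function(config, patient_id, seed, h = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(h)) h <- if (config$regime == "homogenizing") 1 else 0
  glob <- global_pool_attributes(config)
  with_seed(seed, {
    m <- sample_int_range(1, config$per_patient_pool)
    n_res <- max(1L, round(config$resident_fraction * m))
    res_idx <- seq_len(n_res)  # nested resident structure across patients
    tr_idx <- sample(length(glob$transient_ids), m - n_res,
                     prob = glob$transient_w)
    taxa <- c(glob$core_ids[res_idx], glob$transient_ids[tr_idx])
    p <- c(glob$core_p[res_idx], glob$transient_p[tr_idx])

    # latent log10 mean abundance rises with detection probability
    mu <- -2 + config$abundance_coupling * stats::qlogis(p) +
      stats::rnorm(m, 0, config$abundance_noise_sd)

    n <- sample_int_range(1, config$n_samples)
    last <- sample_int_range(1, config$duration_days)
    day <- c(0L, if (n > 2) sort(sample(seq_len(last - 1), n - 2)), last)

    template <- stats::rbinom(m, 1, p) == 1
    pres <- matrix(FALSE, m, n)
    # drift component: stationary two-state Markov chain per taxon
    state <- stats::rbinom(m, 1, p) == 1
    pres_template <- function() {
      flip <- stats::runif(m) < config$flip_noise
      xor(template, flip)
    }
    for (j in seq_len(n)) {
      if (j > 1) {
        rho <- exp(-(day[j] - day[j - 1]) / config$drift_tau_days)
        stay <- stats::runif(m) < rho
        fresh <- stats::rbinom(m, 1, p) == 1
        state <- ifelse(stay, state, fresh)
      }
      if (h >= 1) pres[, j] <- pres_template()
      else if (h <= 0) pres[, j] <- state
      else {
        use_t <- stats::runif(m) < h
        pres[, j] <- ifelse(use_t, pres_template(), state)
      }
      if (!any(pres[, j])) pres[which.max(p), j] <- TRUE  # no empty samples
    }

    ab <- matrix(0, m, n, dimnames = list(
      taxa, paste0(patient_id, "_s", sprintf("%02d", seq_len(n)))))
    for (j in seq_len(n)) {
      det <- pres[, j]
      ab[det, j] <- 10^mu[det] *
        stats::rlnorm(sum(det), 0, config$lognormal_sigma)
    }
    samples <- data.frame(sample_id = colnames(ab),
                          collection_day = day,
                          sample_type = "sputum",
                          stringsAsFactors = FALSE)
    taxa_time_series(patient_id, ab, samples)
  })
}

#' Generate a full synthetic cohort with clinical metadata
#'
#' Generates `n_patients` paediatric-like and `n_patients` adult-like
#' patients. %FEV1 is normal (truncated positive) with the configured cohort
#' mean and SD; exacerbation counts are Poisson with log rate
#' `exacerbation_intercept + exacerbation_link * %FEV1`. When
#' `h_fev1_coupling` is nonzero the per-patient regime mixing weight is tied
#' to standardized %FEV1 on the logit scale.
#'
#' @param config A [generator_config()].
#' @param seed Integer master seed.
#' @return A `cohort_dataset` with metadata.
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "generator_config"))
  cohorts <- names(config$fev1)
  meta <- with_seed(hash_seed("clinical", master_seed = seed), {
    do.call(rbind, lapply(cohorts, function(co) {
      pars <- config$fev1[[co]]
      fv <- stats::rnorm(config$n_patients, pars[["mean"]], pars[["sd"]])
      while (any(fv <= 0))
        fv[fv <= 0] <- stats::rnorm(sum(fv <= 0), pars[["mean"]], pars[["sd"]])
      rate <- exp(config$exacerbation_intercept + config$exacerbation_link * fv)
      data.frame(
        patient_id = sprintf("%s%02d", substr(co, 1, 1), seq_len(config$n_patients)),
        cohort = co,
        mean_fev1 = round(fv, 1),
        fev1_sd = round(abs(stats::rnorm(config$n_patients, 5, 3)) + 0.5, 1),
        exacerbations = stats::rpois(config$n_patients, rate),
        stringsAsFactors = FALSE)
    }))
  })
  series <- lapply(seq_len(nrow(meta)), function(i) {
    h <- config$h_base
    if (!is.null(h) && config$h_fev1_coupling != 0) {
      pars <- config$fev1[[meta$cohort[i]]]
      z <- (meta$mean_fev1[i] - pars[["mean"]]) / pars[["sd"]]
      h <- stats::plogis(stats::qlogis(h) + config$h_fev1_coupling * z)
    }
    generate_patient_series(config, meta$patient_id[i],
                            seed = hash_seed(meta$patient_id[i], master_seed = seed),
                            h = h)
  })
  cohort_dataset(series, meta)
}

#' Clinical characteristics of the 30 study patients
#'
#' Packaged transcription of the study's clinical table: patient id, cohort,
#' mean %FEV1 over the study, its SD, and the number of acute pulmonary
#' exacerbations.
#'
#' @return Data frame of 30 records (15 paediatric, 15 adult).
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_clinical.tsv", package = "lungturnover",
                      mustWork = TRUE)
  read_clinical_metadata(path)
}
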