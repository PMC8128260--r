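#' Configuration for the synthetic MRD cohort generator
#'
#' Builds and validates the parameter set of the synthetic cohort. Defaults
#' describe a resected colorectal-liver-metastasis MRD study: ~85% of
#' patients ctDNA-positive before any treatment, ~24% positive after
#' surgery, a log-normal baseline mutant allele fraction with median 1.86%
#' (IQR roughly 0.44-8.2%), a multiplicative per-cycle MAF decay under
#' neoadjuvant chemotherapy amounting to roughly 40-fold across three
#' cycle-to-cycle steps, and exponential recurrence hazards giving about a
#' 6-fold recurrence-free-survival hazard ratio by postoperative ctDNA
#' status.
#'
#' @param n_patients number of patients.
#' @param cohort2_fraction probability a patient is enrolled in the
#'   neoadjuvant arm (cohort 2; serial TC2-TC4 draws before surgery).
#' @param p_baseline_pos probability of detectable ctDNA at baseline (T0).
#' @param p_postop_pos_given_baseline_pos probability of postoperative MRD
#'   (detectable ctDNA at TP) given baseline positivity; baseline-negative
#'   patients are modelled as MRD-negative.
#' @param baseline_maf_log_mean,baseline_maf_log_sd natural-log-scale mean
#'   and SD of the baseline MAF (as a fraction) among baseline-positive
#'   patients. Defaults give median 1.86% and quartiles near 0.44%/8.2%.
#' @param per_cycle_decay multiplicative change in true MAF per neoadjuvant
#'   chemotherapy cycle, in (0, 1]. Default 0.29 (~40-fold over T0->TC4).
#' @param maf_noise_log_sd SD of within-patient log-normal noise applied to
#'   the true MAF at each serial timepoint.
#' @param hazard_rfs_pos,hazard_rfs_neg exponential recurrence hazards per
#'   month from surgery for postoperative ctDNA-positive / -negative
#'   patients. Defaults 0.030 and 0.005 (hazard ratio 6).
#' @param hazard_death_given_recurrence per-month hazard of death after
#'   recurrence.
#' @param hazard_death_background per-month hazard of death without
#'   recurrence (these deaths are censored for RFS).
#' @param admin_censor_months administrative end of follow-up, months from
#'   surgery, for the last-enrolled patient horizon.
#' @param accrual_months enrolment window; each patient's administrative
#'   censoring time is uniform on
#'   \code{[admin_censor_months - accrual_months, admin_censor_months]}.
#' @param p_adjuvant probability a patient receives adjuvant chemotherapy
#'   (and therefore has a TEOT sample).
#' @param p_clear_adjuvant probability an MRD-positive patient clears ctDNA
#'   by end of adjuvant chemotherapy.
#' @param uid_depth_mean mean number of UID families interrogated per assay.
#' @param reads_per_family_mean mean reads per UID family (minimum 1).
#' @param seq_error_rate per-read probability that the base call at the
#'   interrogated nucleotide is flipped.
#' @param seed integer seed; all randomness in the generator flows from it
#'   through per-patient substreams.
#'
#' @return a validated list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_patients = 54,
                          cohort2_fraction = 23 / 54,
                          p_baseline_pos = 0.85,
                          p_postop_pos_given_baseline_pos = 0.28,
                          baseline_maf_log_mean = log(0.0186),
                          baseline_maf_log_sd = 2.17,
                          per_cycle_decay = 0.29,
                          maf_noise_log_sd = 0.5,
                          hazard_rfs_pos = 0.030,
                          hazard_rfs_neg = 0.005,
                          hazard_death_given_recurrence = 0.03,
                          hazard_death_background = 0.001,
                          admin_censor_months = 82,
                          accrual_months = 42,
                          p_adjuvant = 0.78,
                          p_clear_adjuvant = 0.27,
                          uid_depth_mean = 5000,
                          reads_per_family_mean = 15,
                          seq_error_rate = 1e-3,
                          seed = 1L) {
  cfg <- list(
    n_patients = n_patients, cohort2_fraction = cohort2_fraction,
    p_baseline_pos = p_baseline_pos,
    p_postop_pos_given_baseline_pos = p_postop_pos_given_baseline_pos,
    baseline_maf_log_mean = baseline_maf_log_mean,
    baseline_maf_log_sd = baseline_maf_log_sd,
    per_cycle_decay = per_cycle_decay,
    maf_noise_log_sd = maf_noise_log_sd,
    hazard_rfs_pos = hazard_rfs_pos, hazard_rfs_neg = hazard_rfs_neg,
    hazard_death_given_recurrence = hazard_death_given_recurrence,
    hazard_death_background = hazard_death_background,
    admin_censor_months = admin_censor_months,
    accrual_months = accrual_months,
    p_adjuvant = p_adjuvant, p_clear_adjuvant = p_clear_adjuvant,
    uid_depth_mean = uid_depth_mean,
    reads_per_family_mean = reads_per_family_mean,
    seq_error_rate = seq_error_rate, seed = seed
  )
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  probs <- c("cohort2_fraction", "p_baseline_pos",
             "p_postop_pos_given_baseline_pos", "p_adjuvant",
             "p_clear_adjuvant", "seq_error_rate")
  for (f in probs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop_field(f, "must be a probability in [0, 1]")
  }
  for (f in c("hazard_rfs_pos", "hazard_rfs_neg",
              "hazard_death_given_recurrence", "hazard_death_background")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stop_field(f, "must be a non-negative hazard")
  }
  for (f in c("n_patients", "uid_depth_mean", "reads_per_family_mean")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stop_field(f, "must be a non-negative count")
  }
  d <- cfg$per_cycle_decay
  if (!is.numeric(d) || length(d) != 1 || is.na(d) || d <= 0 || d > 1)
    stop_field("per_cycle_decay", "must lie in (0, 1]")
  for (f in c("baseline_maf_log_sd", "maf_noise_log_sd",
              "admin_censor_months", "accrual_months")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stop_field(f, "must be non-negative")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed))
    stop_field("seed", "must be a single integer")
  invisible(cfg)
}

DAYS_PER_MONTH <- 30.4375

#' Simulate a synthetic MRD cohort
#'
#' Generates a patient sheet, a serial plasma sample sheet and the underlying
#' simulated truth. Every patient has a baseline (T0) sample; cohort-2
#' patients additionally have pre-cycle draws TC2-TC4; the postoperative TP
#' sample is drawn 28-59 days after surgery; patients on adjuvant
#' chemotherapy have an end-of-treatment (TEOT) sample and everyone has
#' follow-up draws until recurrence, death or administrative censoring.
#'
#' Trajectory model: baseline-positive patients start from a log-normal MAF;
#' during neoadjuvant chemotherapy the true MAF is multiplied by
#' \code{per_cycle_decay} each cycle with log-normal within-patient noise.
#' Patients destined to be MRD-negative after surgery clear their ctDNA at a
#' cycle drawn uniformly from \{2,3,4\} (cohort 2), so the detection rate
#' declines across cycles while MRD-positive patients stay detectable.
#' Recurrence times are exponential with hazard keyed to postoperative MRD
#' status; deaths follow recurrence with their own exponential hazard, with a
#' small background death hazard; administrative censoring spreads over the
#' accrual window.
#'
#' Observed supermutant / wild-type UID counts are drawn per sample:
#' \code{depth ~ Poisson(uid_depth_mean)}, mutant templates
#' \code{Binomial(depth, maf/(1+maf))} (so that supermutant/wild-type ratio
#' has expectation MAF), plus sequencing-error-derived false supermutants at
#' the per-family miscall rate implied by \code{seq_error_rate} and the
#' >90% consensus rule.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return list with elements \code{patients} (data.frame, one row per
#'   patient with the clinicopathologic covariates and outcome days),
#'   \code{samples} (data.frame: patient_id, timepoint, day, supermutants,
#'   wildtype_uids), and \code{truth} (per-patient simulated truth:
#'   MRD indicator, true MAFs, event months).
#' @export
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- as.integer(config$n_patients)
  empty_patients <- data.frame(
    patient_id = character(), cohort = integer(), age_years = numeric(),
    sex = character(), n_liver_mets = integer(), synchronous = integer(),
    interval_gt12m = integer(), primary_side = character(),
    n_stage = character(), differentiation = character(),
    cea_baseline_elevated = integer(), cea_postop_elevated = integer(),
    resection_margin = character(), surgery_day = integer(),
    recurrence_day = integer(), death_day = integer(),
    last_followup_day = integer(), stringsAsFactors = FALSE
  )
  empty_samples <- data.frame(
    patient_id = character(), timepoint = character(), day = integer(),
    supermutants = integer(), wildtype_uids = integer(),
    true_maf = numeric(), stringsAsFactors = FALSE
  )
  empty_truth <- data.frame(
    patient_id = character(), baseline_pos = logical(), mrd = logical(),
    maf_t0 = numeric(), maf_tp = numeric(), clearance_cycle = integer(),
    cleared_adjuvant = logical(), recurrence_month = numeric(),
    death_month = numeric(), censor_month = numeric(),
    stringsAsFactors = FALSE
  )
  if (n == 0) {
    return(list(patients = empty_patients, samples = empty_samples,
                truth = empty_truth))
  }

  # per-family probability that sequencing error alone fabricates a
  # supermutant (all-but-<10% of reads flipped); expectation over the
  # shifted-Poisson family-size distribution, truncated at sizes with
  # non-negligible mass
  p_false_super <- false_supermutant_rate(config$reads_per_family_mean,
                                          config$seq_error_rate)

  pat_rows <- vector("list", n)
  samp_rows <- vector("list", n)
  truth_rows <- vector("list", n)

  for (i in seq_len(n)) {
    res <- with_seed(substream_seed(config$seed, i),
                     simulate_patient(i, config, p_false_super))
    pat_rows[[i]] <- res$patient
    samp_rows[[i]] <- res$samples
    truth_rows[[i]] <- res$truth
  }
  list(patients = do.call(rbind, pat_rows),
       samples = do.call(rbind, samp_rows),
       truth = do.call(rbind, truth_rows))
}

# P(UID family miscalled supermutant | wild-type template): needs strictly
# more than 90% of reads flipped. Marginalized over family size 1+Pois(m-1),
# with families of a single read treated as ambiguous by the caller
# (min_family_reads = 2), hence excluded here.
false_supermutant_rate <- function(reads_per_family_mean, seq_error_rate,
                                   min_family_reads = 2) {
  if (seq_error_rate == 0) return(0)
  lambda <- max(reads_per_family_mean - 1, 0)
  sizes <- 1:max(ceiling(lambda + 10 * sqrt(lambda + 1)), 4)
  wts <- stats::dpois(sizes - 1, lambda)
  p_flip <- vapply(sizes, function(s) {
    if (s < min_family_reads) return(0)
    k_min <- floor(0.9 * s) + 1          # smallest count with k/s > 0.9
    stats::pbinom(k_min - 1, s, seq_error_rate, lower.tail = FALSE)
  }, numeric(1))
  sum(wts * p_flip)
}

simulate_patient <- function(i, cfg, p_false_super) {
  pid <- sprintf("P%03d", i)
  cohort <- if (runif(1) < cfg$cohort2_fraction) 2L else 1L

  # clinicopathologic covariates: marginals typical of a resectable-CRLM
  # cohort (median age ~64, 70% male, 39% multiple metastases, ...)
  age <- round(min(max(rnorm(1, 63, 11), 30), 85), 1)
  sex <- if (runif(1) < 0.70) "M" else "F"
  n_mets <- if (runif(1) < 0.39) sample(2:4, 1) else 1L
  synchronous <- as.integer(runif(1) < 0.46)
  interval_gt12m <- as.integer(runif(1) < 0.41)
  primary_side <- if (runif(1) < 0.74) "left" else "right"
  n_stage <- if (runif(1) < 0.44) "N+" else "N0"
  differentiation <- if (runif(1) < 0.11) "poor" else "well-moderate"
  cea_baseline <- as.integer(runif(1) < 0.54)
  margin <- if (runif(1) < 0.09) "R1" else "R0"

  baseline_pos <- runif(1) < cfg$p_baseline_pos
  maf0 <- if (baseline_pos)
    rlnorm(1, cfg$baseline_maf_log_mean, cfg$baseline_maf_log_sd) else 0
  maf0 <- min(maf0, 1.5)  # MAF = mutant/wild-type can exceed 1, cap the tail
  mrd <- baseline_pos && runif(1) < cfg$p_postop_pos_given_baseline_pos
  # postoperative residual: log-normal with median 0.09% MAF, floored near
  # the single-molecule scale of the assay (~2 mutant templates at the
  # default depth) so that MRD-positive means detectable residual disease
  maf_tp <- if (mrd)
    max(rlnorm(1, log(9e-4), 1.5), 2 / max(cfg$uid_depth_mean, 10)) else 0

  # neoadjuvant clearance: MRD-negative-destined patients clear at a cycle
  # drawn uniformly from {2,3,4}; MRD-positive patients stay detectable
  clearance_cycle <- NA_integer_
  if (cohort == 2L && baseline_pos && !mrd)
    clearance_cycle <- sample(2:4, 1)

  surgery_day <- if (cohort == 2L) 70L else 14L

  receives_adjuvant <- runif(1) < cfg$p_adjuvant
  cleared_adjuvant <- mrd && receives_adjuvant && runif(1) < cfg$p_clear_adjuvant

  # outcomes, months from surgery
  h_rfs <- if (mrd) cfg$hazard_rfs_pos else cfg$hazard_rfs_neg
  rec_month <- if (h_rfs > 0) rexp(1, h_rfs) else Inf
  death_bg <- if (cfg$hazard_death_background > 0)
    rexp(1, cfg$hazard_death_background) else Inf
  death_after_rec <- if (cfg$hazard_death_given_recurrence > 0)
    rec_month + rexp(1, cfg$hazard_death_given_recurrence) else Inf
  death_month <- min(death_bg, death_after_rec)
  if (death_month < rec_month) rec_month <- Inf  # died first, no recurrence
  # floor event times at ~3 days / 1 week so observed days stay positive
  rec_month <- max(rec_month, 0.1)
  death_month <- max(death_month, 0.25)
  censor_month <- runif(1, max(cfg$admin_censor_months - cfg$accrual_months, 0),
                        cfg$admin_censor_months)

  obs_end <- min(death_month, censor_month)
  rec_day <- if (is.finite(rec_month) && rec_month <= obs_end)
    surgery_day + as.integer(round(rec_month * DAYS_PER_MONTH)) else NA_integer_
  death_day <- if (is.finite(death_month) && death_month <= censor_month)
    surgery_day + as.integer(round(death_month * DAYS_PER_MONTH)) else NA_integer_
  last_fu_day <- surgery_day + as.integer(round(obs_end * DAYS_PER_MONTH))

  patient <- data.frame(
    patient_id = pid, cohort = cohort, age_years = age, sex = sex,
    n_liver_mets = as.integer(n_mets), synchronous = synchronous,
    interval_gt12m = interval_gt12m, primary_side = primary_side,
    n_stage = n_stage, differentiation = differentiation,
    cea_baseline_elevated = cea_baseline,
    cea_postop_elevated = as.integer(mrd && runif(1) < 0.17),
    resection_margin = margin, surgery_day = surgery_day,
    recurrence_day = rec_day, death_day = death_day,
    last_followup_day = last_fu_day, stringsAsFactors = FALSE
  )

  # serial true MAFs
  tp_labels <- "T0"; tp_days <- 0L; tp_maf <- maf0
  if (cohort == 2L) {
    for (cyc in 2:4) {
      cleared <- !is.na(clearance_cycle) && cyc >= clearance_cycle
      m <- if (!baseline_pos || cleared) 0 else
        maf0 * cfg$per_cycle_decay^(cyc - 1) *
          rlnorm(1, 0, cfg$maf_noise_log_sd)
      tp_labels <- c(tp_labels, paste0("TC", cyc))
      tp_days <- c(tp_days, (cyc - 1L) * 14L)
      tp_maf <- c(tp_maf, m)
    }
  }
  tp_day <- surgery_day + sample(28:59, 1)
  tp_labels <- c(tp_labels, "TP"); tp_days <- c(tp_days, tp_day)
  tp_maf <- c(tp_maf, maf_tp)

  if (receives_adjuvant) {
    teot_day <- surgery_day + if (cohort == 2L) 120L else 180L
    m_teot <- if (!mrd || cleared_adjuvant) 0 else
      maf_tp * rlnorm(1, 0, cfg$maf_noise_log_sd)
    tp_labels <- c(tp_labels, "TEOT"); tp_days <- c(tp_days, teot_day)
    tp_maf <- c(tp_maf, m_teot)
  }

  fu_days <- surgery_day + c(270L, 365L, 550L, 730L)
  horizon <- surgery_day + obs_end * DAYS_PER_MONTH
  if (!is.na(rec_day)) horizon <- min(horizon, rec_day)
  fu_days <- fu_days[fu_days <= horizon]
  if (length(fu_days)) {
    for (k in seq_along(fu_days)) {
      months_post_tp <- (fu_days[k] - tp_day) / DAYS_PER_MONTH
      m <- if (mrd && !cleared_adjuvant)
        min(maf_tp * 1.25^months_post_tp, 0.5) else 0
      tp_labels <- c(tp_labels, paste0("FU", k))
      tp_days <- c(tp_days, fu_days[k])
      tp_maf <- c(tp_maf, m)
    }
  }

  counts <- t(vapply(tp_maf, function(m)
    draw_sample_counts(m, cfg$uid_depth_mean, p_false_super), numeric(2)))
  samples <- data.frame(
    patient_id = pid, timepoint = tp_labels, day = as.integer(tp_days),
    supermutants = as.integer(counts[, 1]),
    wildtype_uids = as.integer(counts[, 2]),
    true_maf = tp_maf, stringsAsFactors = FALSE
  )

  truth <- data.frame(
    patient_id = pid, baseline_pos = baseline_pos, mrd = mrd,
    maf_t0 = maf0, maf_tp = maf_tp, clearance_cycle = clearance_cycle,
    cleared_adjuvant = cleared_adjuvant,
    recurrence_month = if (is.finite(rec_month)) rec_month else NA_real_,
    death_month = if (is.finite(death_month)) death_month else NA_real_,
    censor_month = censor_month, stringsAsFactors = FALSE
  )
  list(patient = patient, samples = samples, truth = truth)
}

# Observed (supermutant, wild-type UID) counts for one assay. A true MAF m
# means mutant templates make up m/(1+m) of molecules, so the called ratio
# supermutant/wild-type has expectation m.
draw_sample_counts <- function(true_maf, uid_depth_mean, p_false_super) {
  depth <- rpois(1, uid_depth_mean)
  if (depth == 0) return(c(0, 0))
  q <- true_maf / (1 + true_maf)
  s <- rbinom(1, depth, q)
  false_s <- if (p_false_super > 0) rbinom(1, depth - s, p_false_super) else 0
  c(s + false_s, depth - s - false_s)
}

#' Simulate a raw UID-family table for one assay
#'
#' Each UID family descends from a single template molecule that is mutant
#' with probability \code{true_maf}; per-read base calls flip with
#' probability \code{seq_error_rate}; family sizes are shifted Poisson with
#' the given mean (minimum one read). (The called supermutant/wild-type
#' ratio is then centred on \code{true_maf/(1-true_maf)}, indistinguishable
#' from \code{true_maf} at the low fractions where the assay operates.)
#'
#' @param n_families number of UID families.
#' @param reads_per_family_mean mean reads per family.
#' @param true_maf true mutant allele fraction (supermutant : wild-type).
#' @param seq_error_rate per-read flip probability.
#' @param seed optional integer seed.
#' @return data.frame with columns family_id, total_reads, alt_reads.
#' @export
simulate_uid_families <- function(n_families, reads_per_family_mean,
                                  true_maf, seq_error_rate, seed = NULL) {
  if (!is.numeric(true_maf) || true_maf < 0 || true_maf > 1)
    stop_field("true_maf", "must be a probability in [0, 1]")
  if (seq_error_rate < 0 || seq_error_rate > 1)
    stop_field("seq_error_rate", "must be a probability in [0, 1]")
  n <- as.integer(n_families)
  with_seed(seed, {
    sizes <- 1L + rpois(n, max(reads_per_family_mean - 1, 0))
    mutant <- rbinom(n, 1L, true_maf) == 1L
    alt <- integer(n)
    alt[mutant] <- rbinom(sum(mutant), sizes[mutant], 1 - seq_error_rate)
    alt[!mutant] <- rbinom(sum(!mutant), sizes[!mutant], seq_error_rate)
    data.frame(family_id = sprintf("F%06d", seq_len(n)),
               total_reads = sizes, alt_reads = alt,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a ctDNA-negative control panel
#'
#' Generates the per-control supermutant / wild-type UID counts used as the
#' null panel of the positivity test, by running the consensus caller over
#' simulated UID families from tumor-free plasma (true MAF 0).
#'
#' @param n_controls number of control samples (the positivity test needs
#'   at least 5).
#' @param uid_depth_mean families per control assay.
#' @param reads_per_family_mean mean reads per family.
#' @param seq_error_rate per-read flip probability.
#' @param seed integer seed.
#' @return data.frame: control_id, supermutants, wildtype_uids.
#' @export
simulate_control_panel <- function(n_controls = 10,
                                   uid_depth_mean = 5000,
                                   reads_per_family_mean = 15,
                                   seq_error_rate = 1e-3,
                                   seed = NULL) {
  rows <- lapply(seq_len(n_controls), function(i) {
    fam <- with_seed(
      if (is.null(seed)) NULL else substream_seed(seed, i),
      simulate_uid_families(rpois(1, uid_depth_mean), reads_per_family_mean,
                            true_maf = 0, seq_error_rate = seq_error_rate))
    cc <- call_families(fam)
    data.frame(control_id = sprintf("C%03d", i),
               supermutants = cc$n_supermutants,
               wildtype_uids = cc$n_wildtype_uids,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
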