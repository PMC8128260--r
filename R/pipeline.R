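#' Read / write the delimited patient and sample sheets
#'
#' Tab-delimited text. Patient sheet columns: patient_id, cohort, age_years,
#' sex, n_liver_mets, synchronous, interval_gt12m, primary_side, n_stage,
#' differentiation, cea_baseline_elevated, cea_postop_elevated,
#' resection_margin, surgery_day, recurrence_day, death_day,
#' last_followup_day (empty = missing). Sample sheet columns: patient_id,
#' timepoint, day, supermutants, wildtype_uids (or family_file).
#'
#' @param path file path.
#' @param x data.frame to write.
#' @return the data.frame (readers) or the path, invisibly (writers).
#' @export
read_patient_sheet <- function(path) {
  if (!file.exists(path))
    stop(sprintf("patient sheet not found: %s", path), call. = FALSE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_patient_sheet
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path))
    stop(sprintf("sample sheet not found: %s", path), call. = FALSE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_patient_sheet
#' @export
write_sheet <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Run the full MRD analysis pipeline
#'
#' Orchestrates simulate (optional) -> positivity calling -> neoadjuvant
#' dynamics -> survival -> cohort statistics, writing a reproducible report
#' bundle. All randomness flows from \code{config$seed}; running the same
#' config twice yields byte-identical outputs.
#'
#' The config is a list (or path to a JSON file) with entries:
#' \describe{
#'   \item{simulate}{logical; generate the cohort with
#'     \code{\link{simulate_cohort}} (default TRUE). Extra generator
#'     settings go under \code{cohort}.}
#'   \item{patients, samples}{paths to sheets when \code{simulate = FALSE}.}
#'   \item{controls}{path to a control-panel table, or "simulate" to
#'     generate one; required for positivity calling.}
#'   \item{alpha, permutations, t0_months, offset, quartile_cutoffs}{
#'     analysis switches with the module defaults.}
#'   \item{seed}{integer master seed (default 1).}
#'   \item{out_dir}{output directory for the report bundle.}
#' }
#'
#' @param config list or JSON path.
#' @return (invisibly) list with the in-memory results and the bundle paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  seed <- config$seed %||% 1L
  alpha <- config$alpha %||% 0.01
  n_perm <- config$permutations %||% 10000
  t0 <- config$t0_months %||% 60
  offset <- config$offset %||% 1e-6
  cutoffs <- config$quartile_cutoffs %||% c(0.15, 1.04, 7.2)
  out_dir <- config$out_dir %||% stop("config missing 'out_dir'",
                                      call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
    message(sprintf(fmt, ...))
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # stage 1: cohort
  cohort <- stage("input", {
    if (isTRUE(config$simulate %||% TRUE)) {
      cfg_args <- config$cohort %||% list()
      cfg_args$seed <- seed
      sim <- simulate_cohort(do.call(cohort_config, cfg_args))
      say("input: simulated %d patients, %d samples",
          nrow(sim$patients), nrow(sim$samples))
      sim
    } else {
      if (is.null(config$patients) || is.null(config$samples))
        stop("patients/samples paths required when simulate = FALSE")
      pats <- read_patient_sheet(config$patients)
      samps <- read_sample_sheet(config$samples)
      say("input: read %d patients, %d samples", nrow(pats), nrow(samps))
      list(patients = pats, samples = samps, truth = NULL)
    }
  })

  controls <- stage("controls", {
    cc <- config$controls
    if (is.null(cc))
      stop("control panel missing: set config$controls to a table path or 'simulate'")
    if (identical(cc, "simulate")) {
      simulate_control_panel(n_controls = config$n_controls %||% 10,
                             seed = substream_seed(seed, 90001))
    } else {
      if (!file.exists(cc)) stop(sprintf("control panel not found: %s", cc))
      read.delim(cc, stringsAsFactors = FALSE)
    }
  })
  say("controls: %d samples, pooled supermutant frequency %.2e",
      nrow(controls),
      sum(controls$supermutants) /
        max(sum(controls$supermutants) + sum(controls$wildtype_uids), 1))

  # stage 2: positivity calling
  calls <- stage("call", {
    call_samples(cohort$samples, controls, n_permutations = n_perm,
                 alpha = alpha, seed = substream_seed(seed, 90002))
  })
  say("call: %d/%d samples ctDNA-positive", sum(calls$positive), nrow(calls))

  # stage 3: neoadjuvant dynamics (cohort-2 trajectories, T0-TC4)
  dynamics <- stage("dynamics", {
    traj <- calls[calls$timepoint %in% c("T0", "TC2", "TC3", "TC4") &
                    calls$patient_id %in%
                      cohort$patients$patient_id[cohort$patients$cohort == 2], ]
    if (nrow(traj) >= 4 && length(unique(traj$patient_id)) >= 2) {
      fit <- select_structure(traj, offset = offset)
      last_tc <- utils::tail(fit$timepoints, 1)
      fc <- fold_change(fit, "T0", last_tc)
      det <- aggregate(positive ~ timepoint, traj,
                       function(x) c(sum(x), length(x)))
      detected <- det$positive[, 1]; n_assessed <- det$positive[, 2]
      trend <- if (nrow(det) >= 2)
        detection_trend_test(detected, n_assessed) else NULL
      list(fit = fit, fold = fc, from = "T0", to = last_tc,
           detection = data.frame(timepoint = det$timepoint,
                                  detected = detected, n = n_assessed),
           trend = trend)
    } else NULL
  })
  if (!is.null(dynamics))
    say("dynamics: %s->%s fold change %.2f (95%% CI %.2f-%.2f)",
        dynamics$from, dynamics$to, dynamics$fold$fold,
        dynamics$fold$ci_low, dynamics$fold$ci_high)

  # stage 4: survival keyed to postoperative (TP) ctDNA status
  surv <- stage("survival", {
    endpoints <- build_endpoints(cohort$patients)
    tp <- calls[calls$timepoint == "TP", c("patient_id", "positive")]
    status <- stats::setNames(tp$positive, tp$patient_id)
    rfs <- endpoints[endpoints$endpoint == "RFS", ]
    rfs$tp_status <- ifelse(is.na(status[rfs$patient_id]), NA,
                            ifelse(status[rfs$patient_id],
                                   "TP-positive", "TP-negative"))
    rfs <- rfs[!is.na(rfs$tp_status), ]
    tab <- rfs_table(rfs$time, rfs$event, rfs$tp_status, t0 = t0)
    km_by_group <- lapply(split(rfs, rfs$tp_status), function(d)
      km_estimate(d$time, d$event)$table)
    uni <- tryCatch(
      cox_fit(rfs$time, rfs$event,
              matrix(as.numeric(rfs$tp_status == "TP-positive"), ncol = 1,
                     dimnames = list(NULL, "tp_positive"))),
      error = function(e) NULL)
    # multivariate with the prespecified confounders available in the sheet
    pats <- cohort$patients[match(rfs$patient_id,
                                  cohort$patients$patient_id), ]
    Xm <- cbind(tp_positive = as.numeric(rfs$tp_status == "TP-positive"),
                cea_elevated = pats$cea_baseline_elevated,
                mets_gt1 = as.numeric(pats$n_liver_mets > 1),
                interval_gt12m = pats$interval_gt12m,
                n_positive = as.numeric(pats$n_stage == "N+"))
    multi <- tryCatch(cox_fit(rfs$time, rfs$event, Xm),
                      error = function(e) NULL)
    list(endpoints = endpoints, rfs_table = tab, km = km_by_group,
         cox_univariate = uni, cox_multivariate = multi)
  })
  say("survival: %d RFS records, %d events",
      sum(surv$endpoints$endpoint == "RFS"),
      sum(surv$endpoints$event[surv$endpoints$endpoint == "RFS"]))

  # stage 5: cohort statistics
  stats_out <- stage("stats", {
    t0_calls <- calls[calls$timepoint == "T0", ]
    tp_calls <- calls[calls$timepoint == "TP", ]
    teot_calls <- calls[calls$timepoint == "TEOT", ]
    pats <- cohort$patients
    recurred <- stats::setNames(!is.na(pats$recurrence_day), pats$patient_id)
    ids <- pats$patient_id
    tr <- transitions_table(data.frame(
      patient_id = ids,
      tp_pos = tp_calls$positive[match(ids, tp_calls$patient_id)],
      teot_pos = teot_calls$positive[match(ids, teot_calls$patient_id)],
      recurred = recurred[ids], stringsAsFactors = FALSE))
    t0_pos <- t0_calls$positive[match(ids, t0_calls$patient_id)]
    assoc <- baseline_assoc_table(pats, t0_pos)
    quart <- data.frame(
      patient_id = t0_calls$patient_id,
      maf_percent = 100 * t0_calls$maf,
      quartile = maf_quartile_strata(100 * t0_calls$maf, cutoffs),
      stringsAsFactors = FALSE)
    list(baseline_positive = sum(t0_pos, na.rm = TRUE),
         baseline_n = sum(!is.na(t0_pos)),
         postop_positive = sum(tp_calls$positive),
         postop_n = nrow(tp_calls),
         transitions = tr, baseline_assoc = assoc, quartiles = quart)
  })
  say("stats: baseline %d/%d positive, postoperative %d/%d positive",
      stats_out$baseline_positive, stats_out$baseline_n,
      stats_out$postop_positive, stats_out$postop_n)

  # report bundle
  bundle <- stage("report", {
    paths <- list()
    wr <- function(x, name) {
      p <- file.path(out_dir, name)
      write_sheet(x, p)
      paths[[name]] <<- p
    }
    wr(cohort$patients, "patients.tsv")
    wr(calls, "calls.tsv")
    for (g in names(surv$km))
      wr(surv$km[[g]], sprintf("km_%s.tsv", gsub("[^A-Za-z0-9]", "_", g)))
    wr(stats_out$transitions, "transitions.tsv")
    wr(stats_out$quartiles, "quartiles.tsv")
    wr(stats_out$baseline_assoc, "baseline_assoc.tsv")

    report <- list(
      dynamics = if (is.null(dynamics)) NULL else list(
        structure = dynamics$fit$chosen_structure,
        aic = dynamics$fit$aic_by_structure,
        coefficients = as.list(dynamics$fit$coefficients),
        robust_se = as.list(stats::setNames(dynamics$fit$robust_se,
                                            names(dynamics$fit$coefficients))),
        fold_change = dynamics$fold,
        contrast = paste(dynamics$from, "->", dynamics$to),
        detection = dynamics$detection,
        trend = dynamics$trend),
      survival = list(
        t0_months = t0,
        by_group = surv$rfs_table$by_group,
        pairwise = surv$rfs_table$pairwise,
        cox_univariate = cox_as_list(surv$cox_univariate),
        cox_multivariate = cox_as_list(surv$cox_multivariate)),
      stats = list(
        baseline_positive = stats_out$baseline_positive,
        baseline_n = stats_out$baseline_n,
        postop_positive = stats_out$postop_positive,
        postop_n = stats_out$postop_n,
        transitions = stats_out$transitions)
    )
    p_report <- file.path(out_dir, "report.json")
    jsonlite::write_json(report, p_report, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE, na = "null")
    paths[["report.json"]] <- p_report

    cfg_for_hash <- config[setdiff(sort(names(config)), "out_dir")]
    p_cfg <- file.path(out_dir, "config.json")
    jsonlite::write_json(cfg_for_hash, p_cfg, auto_unbox = TRUE,
                         pretty = TRUE, na = "null")
    paths[["config.json"]] <- p_cfg
    provenance <- list(
      config_hash = unname(tools::md5sum(p_cfg)),
      seed = seed,
      package = "mrdliquid",
      package_version = as.character(packageVersion("mrdliquid")),
      r_version = paste(R.version$major, R.version$minor, sep = "."))
    p_prov <- file.path(out_dir, "provenance.json")
    jsonlite::write_json(provenance, p_prov, auto_unbox = TRUE,
                         pretty = TRUE)
    paths[["provenance.json"]] <- p_prov
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
    paths[["pipeline.log"]] <- file.path(out_dir, "pipeline.log")
    paths
  })

  invisible(list(cohort = cohort, controls = controls, calls = calls,
                 dynamics = dynamics, survival = surv, stats = stats_out,
                 bundle = bundle, out_dir = out_dir))
}

cox_as_list <- function(fit) {
  if (is.null(fit)) return(NULL)
  list(covariate = names(fit$coefficients),
       coef = unname(fit$coefficients),
       hr = unname(fit$hazard_ratio),
       ci_low = unname(fit$ci_low), ci_high = unname(fit$ci_high),
       p = unname(fit$p_value),
       converged = fit$converged, separation = fit$separation)
}
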