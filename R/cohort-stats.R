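#' Two-sample test of proportions
#'
#' Pooled-variance z-statistic for the difference of two binomial
#' proportions, with a two-sided normal p-value (the classic large-sample
#' test used for baseline-characteristic comparisons).
#'
#' @param x1,n1 successes and total in group 1.
#' @param x2,n2 successes and total in group 2.
#' @return list: \code{z}, \code{p_value}, \code{p1}, \code{p2}.
#' @export
two_proportion_test <- function(x1, n1, x2, n2) {
  if (n1 < 1 || n2 < 1) stop("zero total", call. = FALSE)
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2)
    stop("successes must lie in [0, total]", call. = FALSE)
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  v <- pp * (1 - pp) * (1 / n1 + 1 / n2)
  z <- if (v > 0) (p1 - p2) / sqrt(v) else 0
  list(z = z, p_value = if (v > 0) 2 * pnorm(-abs(z)) else 1,
       p1 = p1, p2 = p2)
}

#' K-sample equality-of-medians test
#'
#' Classifies every value as above / not above the grand median (ties count
#' as "not above") and tests the resulting group-by-classification
#' contingency table with a chi-square statistic, applying the Yates
#' continuity correction when there are exactly two groups.
#'
#' @param groups list of numeric vectors, one per group (each nonempty).
#' @return list: \code{chi2}, \code{df}, \code{p_value},
#'   \code{grand_median}.
#' @export
median_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) == 0))
    stop("empty group", call. = FALSE)
  all_v <- unlist(groups)
  med <- median(all_v)
  above <- vapply(groups, function(g) sum(g > med), numeric(1))
  not_above <- vapply(groups, function(g) sum(g <= med), numeric(1))
  G <- length(groups)
  if (sum(above) == 0 || sum(not_above) == 0)
    return(list(chi2 = 0, df = G - 1, p_value = 1, grand_median = med))
  obs <- rbind(above, not_above)
  exp_ <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  dev <- abs(obs - exp_)
  if (G == 2) dev <- pmax(dev - 0.5, 0)   # Yates continuity correction
  chi2 <- sum(dev^2 / exp_)
  list(chi2 = chi2, df = G - 1,
       p_value = pchisq(chi2, G - 1, lower.tail = FALSE),
       grand_median = med)
}

#' Bonferroni-adjusted significance threshold
#'
#' \code{alpha / n_comparisons}, reported to two significant figures the way
#' such thresholds are quoted in baseline tables.
#'
#' @param alpha family-wise level (default 0.05).
#' @param n_comparisons number of comparisons (>= 1).
#' @return the adjusted threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_comparisons) {
  if (n_comparisons < 1) stop("n_comparisons must be >= 1", call. = FALSE)
  signif(alpha / n_comparisons, 2)
}

#' Monte-Carlo power of a two-sided Fisher exact test
#'
#' Simulates the two-arm MRD design: of \code{n_enrolled} patients a
#' fraction drops out, each analyzable patient is ctDNA-positive with
#' probability \code{allocation_pos} (2:1 positive:negative by default),
#' recurrence-free status at 2 years is Bernoulli with the status-specific
#' probability, and each replicate applies a two-sided Fisher exact test to
#' the status-by-recurrence 2x2 table. Power is the fraction of replicates
#' with p below \code{alpha}. Identical tables are evaluated once and
#' reused.
#'
#' @param n_enrolled enrolled sample size (default 25).
#' @param dropout_rate dropout fraction (default 0.2).
#' @param allocation_pos probability a patient is ctDNA-positive
#'   (default 2/3); with \code{fixed_margin = TRUE} the positive count is
#'   fixed at \code{round(n * allocation_pos)} instead.
#' @param rfs_pos,rfs_neg 2-year recurrence-free probabilities by ctDNA
#'   status (defaults 0.20 and 0.90).
#' @param alpha significance level (default 0.05).
#' @param n_reps Monte-Carlo replicates (>= 1000; default 10000).
#' @param fixed_margin fix the allocation margin instead of binomial draws.
#' @param seed optional integer seed.
#' @return list: \code{power}, \code{mc_ci} (95% Monte-Carlo interval),
#'   \code{n_analyzable}, \code{n_reps}.
#' @export
fisher_power <- function(n_enrolled = 25, dropout_rate = 0.2,
                         allocation_pos = 2 / 3,
                         rfs_pos = 0.20, rfs_neg = 0.90,
                         alpha = 0.05, n_reps = 10000,
                         fixed_margin = FALSE, seed = NULL) {
  if (n_reps < 1000) stop("n_reps must be >= 1000", call. = FALSE)
  for (f in c("dropout_rate", "allocation_pos", "rfs_pos", "rfs_neg",
              "alpha")) {
    v <- get(f)
    if (v < 0 || v > 1) stop_field(f, "must be a probability in [0, 1]")
  }
  n <- round(n_enrolled * (1 - dropout_rate))
  with_seed(seed, {
    n_pos <- if (fixed_margin) rep(round(n * allocation_pos), n_reps)
             else rbinom(n_reps, n, allocation_pos)
    rf_pos <- rbinom(n_reps, n_pos, rfs_pos)
    rf_neg <- rbinom(n_reps, n - n_pos, rfs_neg)
    key <- paste(n_pos, rf_pos, rf_neg)
    uk <- !duplicated(key)
    p_unique <- mapply(function(np, a, b) {
      stats::fisher.test(matrix(c(a, np - a, b, (n - np) - b), nrow = 2))$p.value
    }, n_pos[uk], rf_pos[uk], rf_neg[uk])
    p <- p_unique[match(key, key[uk])]
    power <- mean(p < alpha)
    se <- sqrt(power * (1 - power) / n_reps)
    list(power = power,
         mc_ci = c(max(power - 1.96 * se, 0), min(power + 1.96 * se, 1)),
         n_analyzable = n, n_reps = n_reps)
  })
}

#' Postoperative to end-of-treatment ctDNA transition table
#'
#' Cross-classifies patients by ctDNA status after surgery (TP) and at end
#' of adjuvant treatment (TEOT) and tallies recurrences per category — the
#' numbers behind a Sankey view of adjuvant-chemotherapy clearance.
#' Patients missing either call are excluded, with reasons recorded in the
#' \code{excluded} attribute.
#'
#' @param calls data.frame with columns \code{patient_id}, \code{tp_pos},
#'   \code{teot_pos} (logical, NA = missing) and \code{recurred} (logical).
#' @return data.frame: category ("TP+/TEOT-", "TP+/TEOT+", "TP-/TEOT+",
#'   "TP-/TEOT-"), \code{n}, \code{n_recurred}; excluded patients in
#'   \code{attr(, "excluded")}.
#' @export
transitions_table <- function(calls) {
  cats <- c("TP+/TEOT-", "TP+/TEOT+", "TP-/TEOT+", "TP-/TEOT-")
  if (nrow(calls) == 0) {
    out <- data.frame(category = cats, n = 0L, n_recurred = 0L,
                      stringsAsFactors = FALSE)
    attr(out, "excluded") <- character(0)
    return(out)
  }
  miss <- is.na(calls$tp_pos) | is.na(calls$teot_pos)
  excluded <- sprintf("%s: missing %s call",
                      calls$patient_id[miss],
                      ifelse(is.na(calls$tp_pos[miss]), "TP", "TEOT"))
  ok <- calls[!miss, , drop = FALSE]
  lab <- paste0("TP", ifelse(ok$tp_pos, "+", "-"),
                "/TEOT", ifelse(ok$teot_pos, "+", "-"))
  out <- data.frame(
    category = cats,
    n = vapply(cats, function(cat) sum(lab == cat), integer(1)),
    n_recurred = vapply(cats, function(cat)
      sum(ok$recurred[lab == cat], na.rm = TRUE), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "excluded") <- excluded
  out
}

#' Stratify baseline MAFs into quartile groups
#'
#' Default cut-offs (MAF in percent) follow the quartile convention
#' Q1 <= 0.15 < Q2 <= 1.04 < Q3 <= 7.2 < Q4, with boundary values assigned
#' to the lower quartile.
#'
#' @param maf_percent baseline MAFs in percent (non-negative).
#' @param cutoffs the three upper boundaries of Q1-Q3.
#' @return factor with levels Q1-Q4.
#' @export
maf_quartile_strata <- function(maf_percent, cutoffs = c(0.15, 1.04, 7.2)) {
  if (any(maf_percent < 0, na.rm = TRUE))
    stop("negative MAF", call. = FALSE)
  if (length(cutoffs) != 3 || is.unsorted(cutoffs))
    stop("cutoffs must be 3 increasing values", call. = FALSE)
  cut(maf_percent, breaks = c(-Inf, cutoffs, Inf),
      labels = c("Q1", "Q2", "Q3", "Q4"), right = TRUE)
}

#' Baseline association table
#'
#' Mirrors a clinical baseline table: for each binary covariate, counts per
#' ctDNA-status group and a two-sample proportion test; for continuous
#' covariates (age), medians per group and the equality-of-medians test;
#' plus the Bonferroni-adjusted threshold for the number of rows.
#'
#' @param patients patient sheet.
#' @param status logical vector (same order) of ctDNA positivity.
#' @param binary_vars names of 0/1 columns to compare.
#' @param continuous_vars names of numeric columns to compare by medians.
#' @return data.frame with one row per covariate and attribute
#'   \code{bonferroni_threshold}.
#' @export
baseline_assoc_table <- function(patients, status,
                                 binary_vars = c("synchronous",
                                                 "interval_gt12m",
                                                 "cea_baseline_elevated"),
                                 continuous_vars = "age_years") {
  status <- as.logical(status)
  rows <- list()
  for (v in continuous_vars) {
    x <- patients[[v]]
    mt <- median_test(list(x[status], x[!status]))
    rows[[v]] <- data.frame(
      variable = v, test = "median",
      summary_pos = sprintf("median %.1f", median(x[status])),
      summary_neg = sprintf("median %.1f", median(x[!status])),
      p_value = mt$p_value, stringsAsFactors = FALSE)
  }
  for (v in binary_vars) {
    x <- patients[[v]]
    tt <- two_proportion_test(sum(x[status]), sum(status),
                              sum(x[!status]), sum(!status))
    rows[[v]] <- data.frame(
      variable = v, test = "two-proportion",
      summary_pos = sprintf("%d/%d", sum(x[status]), sum(status)),
      summary_neg = sprintf("%d/%d", sum(x[!status]), sum(!status)),
      p_value = tt$p_value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  attr(out, "bonferroni_threshold") <-
    bonferroni_threshold(0.05, nrow(out))
  out
}
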