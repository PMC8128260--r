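#' Log-transform mutant allele fractions with a zero offset
#'
#' Natural log of the MAF; zero-valued MAFs are logged at a small fixed
#' offset (default 1e-6) so undetectable samples stay in the model. Set
#' \code{add_offset_to_all = TRUE} for the \code{log(maf + offset)} variant.
#'
#' @param maf numeric vector of MAFs (fractions or percent, caller's choice;
#'   units shift the intercept only, never fold changes).
#' @param offset value substituted for zeros before logging.
#' @param add_offset_to_all add the offset to every value instead.
#' @return numeric vector of log-MAFs.
#' @export
log_transform_maf <- function(maf, offset = 1e-6, add_offset_to_all = FALSE) {
  if (any(maf < 0, na.rm = TRUE)) stop("negative MAF", call. = FALSE)
  if (add_offset_to_all) return(log(maf + offset))
  ifelse(maf > 0, log(maf), log(offset))
}

TIMEPOINT_LEVELS <- c("T0", "TC2", "TC3", "TC4", "TP", "TEOT")

#' Mixed-effects model of longitudinal log-MAF
#'
#' Fits log-MAF against timepoint (categorical, T0 reference) with a random
#' intercept per patient, or a random slope on the cycle index, by maximum
#' likelihood. Fixed-effect standard errors are cluster-robust (CR1
#' sandwich, clustered on patient) to operationalize
#' heteroscedasticity-consistent inference over serial measurements.
#'
#' @param points data.frame with columns \code{patient_id},
#'   \code{timepoint} (labels among T0, TC2, TC3, TC4, TP, TEOT) and either
#'   \code{log_maf} or \code{maf} (zeros handled by
#'   \code{\link{log_transform_maf}}).
#' @param structure "intercepts" (random intercept) or "slopes" (random
#'   intercept and slope on cycle index).
#' @param offset zero-MAF offset passed to the log transform.
#' @return object of class \code{dynamics_fit}: coefficients, robust
#'   covariance and SEs, AIC, chosen structure, the timepoint levels
#'   present, number of patients, and the underlying \code{lmer} fit.
#' @export
fit_lmm <- function(points, structure = c("intercepts", "slopes"),
                    offset = 1e-6) {
  structure <- match.arg(structure)
  if (!all(c("patient_id", "timepoint") %in% names(points)))
    stop("points need columns patient_id, timepoint", call. = FALSE)
  if (!"log_maf" %in% names(points)) {
    if (!"maf" %in% names(points))
      stop("points need a log_maf or maf column", call. = FALSE)
    points$log_maf <- log_transform_maf(points$maf, offset)
  }
  points <- points[complete.cases(points[, c("patient_id", "timepoint",
                                             "log_maf")]), , drop = FALSE]
  lev <- TIMEPOINT_LEVELS[TIMEPOINT_LEVELS %in% unique(points$timepoint)]
  if (length(lev) < 2) stop("need at least 2 timepoints", call. = FALSE)
  points$timepoint <- factor(points$timepoint, levels = lev)
  points$cycle <- as.numeric(points$timepoint) - 1
  tab <- table(points$patient_id)
  if (sum(tab >= 2) < 2)
    stop("need at least 2 patients with at least 2 timepoints", call. = FALSE)

  form <- if (structure == "intercepts")
    log_maf ~ timepoint + (1 | patient_id)
  else
    log_maf ~ timepoint + (1 + cycle | patient_id)

  fit <- withCallingHandlers(
    lme4::lmer(form, data = points, REML = FALSE),
    warning = function(w) invokeRestart("muffleWarning"))

  if (structure == "slopes" && lme4::isSingular(fit, tol = 1e-4)) {
    warning("singular random-slopes fit; falling back to random intercepts",
            call. = FALSE)
    return(fit_lmm(points, "intercepts", offset))
  }

  beta <- lme4::fixef(fit)
  vc <- cluster_robust_vcov(fit, points$patient_id)
  structure(list(
    coefficients = beta,
    vcov_robust = vc,
    robust_se = sqrt(diag(vc)),
    aic = AIC(fit),
    chosen_structure = structure,
    timepoints = lev,
    n_patients = length(tab),
    n_obs = nrow(points),
    model = fit
  ), class = "dynamics_fit")
}

# CR1 cluster-robust sandwich for the fixed effects of a Gaussian lmer fit:
# bread (X' V^-1 X)^-1 with V_i = Z_i G Z_i' + sigma^2 I per cluster, meat
# from per-cluster marginal residuals, G/(G-1) small-sample factor.
cluster_robust_vcov <- function(fit, cluster) {
  X <- lme4::getME(fit, "X")
  y <- lme4::getME(fit, "y")
  Z <- as.matrix(lme4::getME(fit, "Z"))
  beta <- lme4::fixef(fit)
  s2 <- stats::sigma(fit)^2
  G_full <- s2 * crossprod(as.matrix(lme4::getME(fit, "Lambdat"))) # q x q
  r <- y - X %*% beta
  cl <- as.character(cluster)
  ids <- unique(cl)
  p <- ncol(X)
  bread_inv <- matrix(0, p, p)
  meat <- matrix(0, p, p)
  for (g in ids) {
    idx <- which(cl == g)
    Xi <- X[idx, , drop = FALSE]
    Zi <- Z[idx, , drop = FALSE]
    Vi <- Zi %*% G_full %*% t(Zi) + diag(s2, length(idx))
    Vinv <- solve(Vi)
    XtVi <- t(Xi) %*% Vinv
    bread_inv <- bread_inv + XtVi %*% Xi
    u <- XtVi %*% r[idx]
    meat <- meat + u %*% t(u)
  }
  bread <- solve(bread_inv)
  ng <- length(ids)
  corr <- if (ng > 1) ng / (ng - 1) else 1
  vc <- corr * bread %*% meat %*% bread
  dimnames(vc) <- list(names(beta), names(beta))
  vc
}

#' Fit both random-effect structures and keep the lower-AIC one
#'
#' Fits the random-intercepts and random-slopes models and returns the fit
#' with the smaller AIC; ties go to the simpler random-intercepts model.
#'
#' @inheritParams fit_lmm
#' @return a \code{dynamics_fit} with \code{aic_by_structure} attached.
#' @export
select_structure <- function(points, offset = 1e-6) {
  fi <- fit_lmm(points, "intercepts", offset)
  fs <- tryCatch(suppressWarnings(fit_lmm(points, "slopes", offset)),
                 error = function(e) NULL)
  aics <- c(intercepts = fi$aic,
            slopes = if (is.null(fs)) NA_real_ else fs$aic)
  chosen <- if (!is.null(fs) && fs$chosen_structure == "slopes" &&
                isTRUE(fs$aic < fi$aic)) fs else fi
  chosen$aic_by_structure <- aics
  chosen
}

#' Fold change between two timepoints from a dynamics fit
#'
#' Exponentiated model contrast: \code{fold = exp(beta_from - beta_to)},
#' with a 95% CI from the cluster-robust SE of the contrast. A fold above 1
#' is a decrease from \code{from} to \code{to}.
#'
#' @param fit a \code{dynamics_fit}.
#' @param from,to timepoint labels present in the fit.
#' @return list: \code{fold}, \code{ci_low}, \code{ci_high}, \code{se_log},
#'   \code{p_value} (Wald, two-sided).
#' @export
fold_change <- function(fit, from = "T0", to = "TC4") {
  lev <- fit$timepoints
  if (!(from %in% lev) || !(to %in% lev))
    stop(sprintf("unknown timepoint: %s",
                 paste(setdiff(c(from, to), lev), collapse = ", ")),
         call. = FALSE)
  cf <- fit$coefficients
  cvec <- stats::setNames(numeric(length(cf)), names(cf))
  term <- function(tp) if (tp == lev[1]) NULL else paste0("timepoint", tp)
  if (!is.null(term(from))) cvec[term(from)] <- 1
  if (!is.null(term(to))) cvec[term(to)] <- cvec[term(to)] - 1
  est <- sum(cvec * cf)
  se <- sqrt(drop(t(cvec) %*% fit$vcov_robust %*% cvec))
  z <- if (se > 0) est / se else 0
  list(fold = exp(est),
       ci_low = exp(est - 1.96 * se),
       ci_high = exp(est + 1.96 * se),
       se_log = se,
       p_value = if (se > 0) 2 * pnorm(-abs(z)) else 1)
}

#' Cochran-Armitage trend test for detection rates across cycles
#'
#' Tests whether the ctDNA detection rate changes monotonically across
#' ordered chemotherapy cycles, using the Cochran-Armitage trend statistic
#' with equally spaced scores and a two-sided normal p-value. Within-patient
#' correlation across cycles is ignored (each cycle's detections are treated
#' as independent binomials), a documented simplification.
#'
#' @param detected number of ctDNA-positive samples per cycle (ordered).
#' @param n number of assessed samples per cycle.
#' @return list: \code{z}, \code{p_value}, \code{rates}.
#' @export
detection_trend_test <- function(detected, n) {
  if (length(detected) != length(n))
    stop("detected and n differ in length", call. = FALSE)
  if (length(n) < 2) stop("need at least 2 cycles", call. = FALSE)
  if (any(detected < 0) || any(detected > n) || any(n < 1))
    stop("need 0 <= detected <= n, n >= 1", call. = FALSE)
  scores <- seq_along(n) - 1
  N <- sum(n)
  pbar <- sum(detected) / N
  if (pbar == 0 || pbar == 1)
    return(list(z = 0, p_value = 1, rates = detected / n))
  T_stat <- sum(detected * scores) - pbar * sum(n * scores)
  v <- pbar * (1 - pbar) * (sum(n * scores^2) - sum(n * scores)^2 / N)
  if (v <= 0) return(list(z = 0, p_value = 1, rates = detected / n))
  z <- T_stat / sqrt(v)
  list(z = z, p_value = 2 * pnorm(-abs(z)), rates = detected / n)
}

#' @export
#' @method print dynamics_fit
print.dynamics_fit <- function(x, ...) {
  cat(sprintf("Longitudinal log-MAF mixed model (random %s)\n",
              x$chosen_structure))
  cat(sprintf("  %d patients, %d observations; AIC %.2f\n",
              x$n_patients, x$n_obs, x$aic))
  tab <- data.frame(estimate = x$coefficients, robust_se = x$robust_se)
  print(round(tab, 4))
  invisible(x)
}
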