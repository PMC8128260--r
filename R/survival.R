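#' Build RFS and OS endpoints from a patient sheet
#'
#' Recurrence-free survival counts locoregional and distant recurrence as
#' events; deaths without recurrence are censored at the time of death.
#' Overall survival counts deaths as events, censoring at last follow-up.
#' Times are months from surgery (days / 30.4375).
#'
#' @param patients patient sheet with columns patient_id, surgery_day,
#'   recurrence_day, death_day, last_followup_day (NA = missing).
#' @param days_per_month day-to-month conversion.
#' @return data.frame: patient_id, endpoint ("RFS"/"OS"), time (months),
#'   event (logical).
#' @export
build_endpoints <- function(patients, days_per_month = 30.4375) {
  need <- c("patient_id", "surgery_day", "recurrence_day", "death_day",
            "last_followup_day")
  if (!all(need %in% names(patients)))
    stop("patient sheet missing outcome columns", call. = FALSE)
  rows <- lapply(seq_len(nrow(patients)), function(i) {
    p <- patients[i, ]
    if (is.na(p$surgery_day)) stop("surgery_day missing", call. = FALSE)
    if (!is.na(p$recurrence_day) && p$recurrence_day < p$surgery_day)
      stop(sprintf("recurrence before surgery for %s", p$patient_id),
           call. = FALSE)
    fu_end <- min(c(p$death_day, p$last_followup_day), na.rm = TRUE)
    if (!is.finite(fu_end) || fu_end <= p$surgery_day)
      stop(sprintf("non-positive follow-up for %s", p$patient_id),
           call. = FALSE)
    if (!is.na(p$recurrence_day)) {
      rfs_t <- (p$recurrence_day - p$surgery_day) / days_per_month
      rfs_e <- TRUE
    } else {
      rfs_t <- (fu_end - p$surgery_day) / days_per_month
      rfs_e <- FALSE
    }
    if (!is.na(p$death_day)) {
      os_t <- (p$death_day - p$surgery_day) / days_per_month
      os_e <- TRUE
    } else {
      os_t <- (p$last_followup_day - p$surgery_day) / days_per_month
      os_e <- FALSE
    }
    rfs_t <- max(rfs_t, 1e-6)
    os_t <- max(os_t, 1e-6)
    data.frame(patient_id = rep(p$patient_id, 2),
               endpoint = c("RFS", "OS"),
               time = c(rfs_t, os_t), event = c(rfs_e, os_e),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Kaplan-Meier product-limit estimate with Greenwood variance of log S
#'
#' @param time event/censoring times (months), all > 0.
#' @param event logical/0-1 event indicator.
#' @return object of class \code{km_curve}: per distinct event time the
#'   at-risk count, event count, survival estimate and Greenwood variance of
#'   \code{log S}, \code{V(t) = sum d_i / (n_i (n_i - d_i))}; plus the
#'   maximum observed follow-up.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0) stop("no records", call. = FALSE)
  if (any(time <= 0)) stop("times must be positive", call. = FALSE)
  event <- as.logical(event)
  ev_times <- sort(unique(time[event]))
  n_risk <- vapply(ev_times, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ev_times, function(t) sum(time == t & event), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  var_log <- cumsum(ifelse(n_risk > n_event,
                           n_event / (n_risk * (n_risk - n_event)), Inf))
  structure(list(
    table = data.frame(time = ev_times, n_risk = n_risk, n_event = n_event,
                       surv = surv, var_log_surv = var_log),
    n = length(time), n_events = sum(event), max_time = max(time)
  ), class = "km_curve")
}

#' Survival and Greenwood variance at a fixed time
#'
#' Right-continuous step-function lookup. Beyond the last observed
#' follow-up the last value is carried forward with
#' \code{extrapolated = TRUE}.
#'
#' @param curve a \code{km_curve}.
#' @param t time in months.
#' @return list: \code{surv}, \code{var_log_surv}, \code{extrapolated}.
#' @export
km_at <- function(curve, t) {
  tab <- curve$table
  idx <- which(tab$time <= t)
  if (length(idx) == 0)
    return(list(surv = 1, var_log_surv = 0, extrapolated = FALSE))
  k <- max(idx)
  list(surv = tab$surv[k], var_log_surv = tab$var_log_surv[k],
       extrapolated = t > curve$max_time)
}

#' Klein two-sample test for difference in survival at a fixed time
#'
#' Compares two Kaplan-Meier curves at a prespecified time using
#' log-transformed survival functions and unpooled Greenwood variances:
#' \code{Z = (log S_A(t0) - log S_B(t0)) / sqrt(V_A(t0) + V_B(t0))}, with a
#' two-sided standard-normal p-value. Designed for settings where a group
#' has no events and a Cox hazard ratio would be infinite.
#'
#' @param time_a,event_a,time_b,event_b per-group times and event flags.
#' @param t0 comparison time in months (e.g. 60 for 5-year survival).
#' @return list: \code{z}, \code{p_value}, \code{surv_a}, \code{surv_b},
#'   \code{var_a}, \code{var_b}.
#' @export
klein_fixed_time_test <- function(time_a, event_a, time_b, event_b, t0) {
  ka <- km_at(km_estimate(time_a, event_a), t0)
  kb <- km_at(km_estimate(time_b, event_b), t0)
  if (ka$surv <= 0 || kb$surv <= 0)
    stop("log transform undefined; use earlier t0", call. = FALSE)
  num <- log(ka$surv) - log(kb$surv)
  den <- sqrt(ka$var_log_surv + kb$var_log_surv)
  z <- if (num == 0) 0 else num / den
  list(z = z, p_value = 2 * pnorm(-abs(z)),
       surv_a = ka$surv, surv_b = kb$surv,
       var_a = ka$var_log_surv, var_b = kb$var_log_surv)
}

#' Cox proportional-hazards regression with exact tie handling
#'
#' Fits the Cox model by damped Newton maximization of the partial
#' likelihood. With \code{ties = "exact"}, each set of d tied events at one
#' time contributes \code{exp(sum eta_D) / e_d({exp(eta_j): j in risk set})}
#' where \code{e_d} is the order-d elementary symmetric polynomial,
#' evaluated with its derivatives by the standard add-one-member recurrence
#' (never by subset enumeration). \code{ties = "breslow"} gives the usual
#' Breslow approximation.
#'
#' Monotone-likelihood separation (a covariate perfectly splitting events)
#' is detected when a coefficient runs beyond \code{separation_bound} with a
#' non-vanishing gradient, and flagged rather than reported as converged.
#'
#' @param time,event survival times (months) and event indicators.
#' @param covariates numeric matrix or data.frame of covariates (binary or
#'   continuous; factors must be pre-coded).
#' @param ties "exact" (default) or "breslow".
#' @param max_iter,tol Newton iteration cap and gradient sup-norm tolerance.
#' @param separation_bound |beta| beyond which separation is declared.
#' @return object of class \code{cox_fit}: \code{coefficients},
#'   \code{hazard_ratio}, \code{se}, \code{ci_low}, \code{ci_high},
#'   \code{p_value}, \code{loglik}, \code{vcov}, \code{converged},
#'   \code{separation}, \code{n}, \code{n_events}, \code{ties}.
#' @export
cox_fit <- function(time, event, covariates, ties = c("exact", "breslow"),
                    max_iter = 50, tol = 1e-8, separation_bound = 15) {
  ties <- match.arg(ties)
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  event <- as.logical(event)
  if (sum(event) == 0) stop("no events", call. = FALSE)
  if (any(apply(X, 2, var) == 0))
    stop("constant covariate", call. = FALSE)
  p <- ncol(X)

  center <- colMeans(X)
  Xc <- sweep(X, 2, center)

  ll_fun <- function(beta) cox_loglik(beta, time, event, Xc, ties)

  beta <- rep(0, p)
  cur <- ll_fun(beta)
  converged <- FALSE
  separation <- FALSE
  for (it in seq_len(max_iter)) {
    g <- cur$grad
    H <- cur$hess
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(-H, g), error = function(e) g) # fallback: ascent
    new_beta <- beta + step
    new <- ll_fun(new_beta)
    halvings <- 0
    while ((!is.finite(new$loglik) || new$loglik < cur$loglik) &&
           halvings < 25) {
      step <- step / 2
      new_beta <- beta + step
      new <- ll_fun(new_beta)
      halvings <- halvings + 1
    }
    beta <- new_beta
    cur <- new
    if (max(abs(beta)) > separation_bound && max(abs(cur$grad)) > 1e-3) {
      separation <- TRUE
      break
    }
  }
  if (!converged && max(abs(cur$grad)) < tol) converged <- TRUE
  # monotone likelihood: a coefficient that has run beyond the bound is
  # diverging even if the gradient has flattened out along its asymptote
  if (max(abs(beta)) > separation_bound) separation <- TRUE

  vcov <- tryCatch(solve(-cur$hess), error = function(e)
    matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(vcov), 0))
  z <- ifelse(se > 0, beta / se, NA_real_)
  names(beta) <- colnames(X)
  structure(list(
    coefficients = beta,
    hazard_ratio = exp(beta),
    se = stats::setNames(se, colnames(X)),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    p_value = 2 * pnorm(-abs(z)),
    loglik = cur$loglik,
    vcov = vcov,
    converged = converged && !separation,
    separation = separation,
    n = length(time), n_events = sum(event), ties = ties
  ), class = "cox_fit")
}

#' Cox partial log-likelihood, gradient and Hessian
#'
#' Exposed for numerical verification; \code{\link{cox_fit}} drives it.
#'
#' @param beta coefficient vector.
#' @param time,event,X data (X a numeric matrix).
#' @param ties "exact" or "breslow".
#' @return list: \code{loglik}, \code{grad}, \code{hess}.
#' @export
cox_loglik <- function(beta, time, event, X, ties = "exact") {
  X <- as.matrix(X)
  p <- ncol(X)
  eta <- drop(X %*% beta)
  ev_times <- sort(unique(time[as.logical(event)]))
  ll <- 0
  grad <- numeric(p)
  hess <- matrix(0, p, p)
  for (t in ev_times) {
    D <- which(time == t & event)
    R <- which(time >= t)
    d <- length(D)
    ll <- ll + sum(eta[D])
    grad <- grad + colSums(X[D, , drop = FALSE])
    if (ties == "breslow" || d == 1) {
      # Breslow term, also the exact term when d = 1
      M <- max(eta[R])
      w <- exp(eta[R] - M)
      s0 <- sum(w)
      s1 <- drop(t(w) %*% X[R, , drop = FALSE])
      s2 <- t(X[R, , drop = FALSE]) %*% (w * X[R, , drop = FALSE])
      ll <- ll - d * (log(s0) + M)
      grad <- grad - d * s1 / s0
      hess <- hess - d * (s2 / s0 - tcrossprod(s1 / s0))
    } else {
      es <- esp_derivs(eta[R], X[R, , drop = FALSE], d)
      ll <- ll - es$log_e
      grad <- grad - es$dlog
      hess <- hess - es$d2log
    }
  }
  list(loglik = ll, grad = grad, hess = hess)
}

#' Elementary symmetric polynomial of exp(eta) with derivatives
#'
#' Computes \code{log e_d(w)}, its gradient and Hessian in beta (through
#' \code{w_j = exp(eta_j)}, \code{eta = X beta}) by the add-one-member
#' recurrence \code{e_k^(m) = e_k^(m-1) + w_m e_(k-1)^(m-1)}, carried along
#' for the first two derivatives. Work is shifted by max(eta) for overflow
#' safety; the shift cancels in all logarithmic derivatives.
#'
#' @param eta linear predictors over the risk set.
#' @param X covariate rows of the risk set.
#' @param d number of tied events.
#' @return list: \code{log_e}, \code{dlog} (p-vector), \code{d2log} (p x p).
#' @export
esp_derivs <- function(eta, X, d) {
  X <- as.matrix(X)
  m <- length(eta)
  p <- ncol(X)
  if (d > m) stop("more tied events than risk-set members", call. = FALSE)
  M <- max(eta)
  w <- exp(eta - M)
  # e[k+1] = e_k; g[[k+1]] p-vector; H[[k+1]] p x p
  e <- c(1, numeric(d))
  g <- lapply(0:d, function(k) numeric(p))
  H <- lapply(0:d, function(k) matrix(0, p, p))
  for (j in seq_len(m)) {
    wj <- w[j]
    xj <- X[j, ]
    for (k in d:1) {
      # order matters: degree k uses pre-update degree k-1
      H[[k + 1]] <- H[[k + 1]] + wj * (tcrossprod(xj) * e[k] +
        tcrossprod(xj, g[[k]]) + tcrossprod(g[[k]], xj) + H[[k]])
      g[[k + 1]] <- g[[k + 1]] + wj * (xj * e[k] + g[[k]])
      e[k + 1] <- e[k + 1] + wj * e[k]
    }
  }
  ed <- e[d + 1]
  dlog <- g[[d + 1]] / ed
  d2log <- H[[d + 1]] / ed - tcrossprod(dlog)
  list(log_e = log(ed) + d * M, dlog = dlog, d2log = d2log)
}

#' Per-group fixed-time survival summary with pairwise Klein tests
#'
#' For each level of a grouping, reports patients, events and the KM
#' survival (with Greenwood variance) at \code{t0} months; runs all pairwise
#' Klein fixed-time tests; and, for groupings where both groups have events,
#' the univariate Cox hazard ratio versus the first level. When a group has
#' no events the hazard ratio is undefined (infinite under partial
#' likelihood) and the Klein test is the reported comparison, which is
#' flagged in the output.
#'
#' @param time,event survival data in months.
#' @param group factor/character group labels.
#' @param t0 fixed comparison time (months), default 60.
#' @param ties tie handling for the Cox fits.
#' @return list: \code{by_group} data.frame, \code{pairwise} data.frame of
#'   Klein tests and Cox HRs (NA with \code{hr_note} when undefined).
#' @export
rfs_table <- function(time, event, group, t0 = 60, ties = "exact") {
  group <- as.character(group)
  levs <- unique(group)
  by_group <- do.call(rbind, lapply(levs, function(g) {
    sel <- group == g
    at <- km_at(km_estimate(time[sel], event[sel]), t0)
    data.frame(group = g, n = sum(sel), n_events = sum(event[sel]),
               surv_t0 = at$surv, var_log_surv_t0 = at$var_log_surv,
               extrapolated = at$extrapolated, stringsAsFactors = FALSE)
  }))
  pairs <- if (length(levs) > 1) combn(levs, 2, simplify = FALSE) else list()
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    a <- group == pr[1]; b <- group == pr[2]
    kl <- tryCatch(
      klein_fixed_time_test(time[a], event[a], time[b], event[b], t0),
      error = function(e) list(z = NA_real_, p_value = NA_real_))
    hr <- NA_real_; hr_lo <- NA_real_; hr_hi <- NA_real_; hr_p <- NA_real_
    note <- ""
    if (sum(event[a]) == 0 || sum(event[b]) == 0) {
      note <- "zero events in a group; hazard ratio undefined, Klein test reported"
    } else {
      sel <- a | b
      fit <- tryCatch(
        cox_fit(time[sel], event[sel],
                matrix(as.numeric(group[sel] == pr[2]), ncol = 1,
                       dimnames = list(NULL, "group")), ties = ties),
        error = function(e) NULL)
      if (!is.null(fit) && !fit$separation) {
        hr <- fit$hazard_ratio[1]; hr_lo <- fit$ci_low[1]
        hr_hi <- fit$ci_high[1]; hr_p <- fit$p_value[1]
      } else if (!is.null(fit) && fit$separation) {
        note <- "separation in Cox fit; Klein test reported"
      }
    }
    data.frame(group_a = pr[1], group_b = pr[2],
               klein_z = kl$z, klein_p = kl$p_value,
               hr = hr, hr_ci_low = hr_lo, hr_ci_high = hr_hi, hr_p = hr_p,
               hr_note = note, stringsAsFactors = FALSE)
  }))
  list(by_group = by_group, pairwise = pairwise, t0 = t0)
}

#' @export
#' @method print cox_fit
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional hazards (%s ties): %d subjects, %d events\n",
              x$ties, x$n, x$n_events))
  if (x$separation) cat("  WARNING: monotone likelihood (separation) detected\n")
  if (!x$converged && !x$separation) cat("  WARNING: did not converge\n")
  tab <- data.frame(coef = x$coefficients, HR = x$hazard_ratio,
                    lower95 = x$ci_low, upper95 = x$ci_high,
                    p = x$p_value)
  print(round(tab, 4))
  invisible(x)
}
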