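mk_patients <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(patient_id = sprintf("P%d", i),
               surgery_day = r[1], recurrence_day = r[2],
               death_day = r[3], last_followup_day = r[4])
  }))
}

test_that("endpoint construction applies the censoring rules", {
  # recurrence day 360, death day 600 (surgery day 0)
  ep <- build_endpoints(mk_patients(c(0, 360, 600, 600)))
  rfs <- ep[ep$endpoint == "RFS", ]; os <- ep[ep$endpoint == "OS", ]
  expect_true(rfs$event); expect_equal(rfs$time, 360 / 30.4375)
  expect_true(os$event); expect_equal(os$time, 600 / 30.4375)

  # death without recurrence: RFS censored at death
  ep <- build_endpoints(mk_patients(c(0, NA, 900, 900)))
  rfs <- ep[ep$endpoint == "RFS", ]
  expect_false(rfs$event); expect_equal(rfs$time, 900 / 30.4375)

  # alive, no recurrence: both censored at last follow-up
  ep <- build_endpoints(mk_patients(c(0, NA, NA, 1500)))
  expect_true(all(!ep$event))
  expect_true(all(ep$time == 1500 / 30.4375))

  expect_error(build_endpoints(mk_patients(c(100, 50, NA, 800))),
               "recurrence before surgery")
})

test_that("product-limit estimate matches its brute-force oracle", {
  # 4 events at distinct times, no censoring
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$table$surv, c(0.75, 0.5, 0.25, 0))

  # all censored -> S = 1 everywhere, zero variance
  km <- km_estimate(c(5, 8, 12), c(0, 0, 0))
  expect_equal(nrow(km$table), 0)
  at <- km_at(km, 10)
  expect_equal(at$surv, 1); expect_equal(at$var_log_surv, 0)

  # fixed fixture with a tie and censoring
  time <- c(1, 2, 2, 3, 5); event <- c(1, 1, 0, 1, 0)
  km <- km_estimate(time, event)
  orc <- oracle_km(time, event)
  expect_equal(km$table$surv, orc$surv, tolerance = 1e-12)
  expect_equal(km$table$var_log_surv, orc$var_log, tolerance = 1e-12)

  # beyond last observed time: carried forward with a flag
  at <- km_at(km, 10)
  expect_true(at$extrapolated)
  expect_equal(at$surv, tail(orc$surv, 1))
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(2)
  for (r in 1:10) {
    t <- sample(1:30, 25, replace = TRUE)
    km <- km_estimate(t, rep(1, 25))
    for (tt in unique(t))
      expect_equal(km_at(km, tt)$surv, mean(t > tt), tolerance = 1e-12)
  }
})

test_that("KM matches survival::survfit on random censored data", {
  skip_if_not_installed("survival")
  set.seed(4)
  t <- round(rexp(60, 0.05), 1) + 0.1
  ev <- rbinom(60, 1, 0.7)
  km <- km_estimate(t, ev)
  sf <- survival::survfit(survival::Surv(t, ev) ~ 1)
  i <- sf$n.event > 0
  expect_equal(km$table$surv, sf$surv[i], tolerance = 1e-12)
  fin <- is.finite(km$table$var_log_surv)
  expect_equal(km$table$var_log_surv[fin], (sf$std.err[i]^2)[fin],
               tolerance = 1e-10)
})

test_that("Klein fixed-time test matches a step-by-step Greenwood computation", {
  # identical groups -> Z = 0, p = 1
  fx <- fixture_surv(1, 20, 0.03)
  same <- klein_fixed_time_test(fx$time, fx$event, fx$time, fx$event, 40)
  expect_equal(same$z, 0); expect_equal(same$p_value, 1)

  # two fixed 20-patient fixtures: compare against the arithmetic oracle
  a <- fixture_surv(11, 20, 0.05, cens = 70)
  b <- fixture_surv(12, 20, 0.015, cens = 70)
  res <- klein_fixed_time_test(a$time, a$event, b$time, b$event, 60)
  oa <- oracle_km_at(a$time, a$event, 60)
  ob <- oracle_km_at(b$time, b$event, 60)
  z_oracle <- (log(oa$surv) - log(ob$surv)) / sqrt(oa$var_log + ob$var_log)
  expect_equal(res$z, z_oracle, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pnorm(-abs(z_oracle)), tolerance = 1e-12)

  # antisymmetry: swapping groups negates Z, preserves p
  swp <- klein_fixed_time_test(b$time, b$event, a$time, a$event, 60)
  expect_equal(swp$z, -res$z, tolerance = 1e-12)
  expect_equal(swp$p_value, res$p_value, tolerance = 1e-12)

  # S(t0) = 0 -> log undefined
  expect_error(
    klein_fixed_time_test(c(1, 2, 3), c(1, 1, 1), c(5, 6), c(0, 0), 10),
    "log transform undefined")
})

test_that("elementary symmetric polynomial recursion matches subset enumeration", {
  set.seed(7)
  for (r in 1:20) {
    m <- sample(3:12, 1)
    d <- sample(1:min(4, m), 1)
    p <- sample(1:3, 1)
    X <- matrix(rnorm(m * p), m, p)
    beta <- rnorm(p, 0, 0.7)
    eta <- drop(X %*% beta)
    es <- esp_derivs(eta, X, d)
    expect_equal(es$log_e, log(oracle_esp(exp(eta), d)), tolerance = 1e-9)
    # gradient and Hessian against central differences of the enumeration
    h <- 1e-5
    for (j in seq_len(p)) {
      bp <- beta; bp[j] <- bp[j] + h
      bm <- beta; bm[j] <- bm[j] - h
      g_num <- (log(oracle_esp(exp(drop(X %*% bp)), d)) -
                  log(oracle_esp(exp(drop(X %*% bm)), d))) / (2 * h)
      expect_equal(es$dlog[j], g_num, tolerance = 1e-5)
    }
  }
})

test_that("exact partial likelihood equals enumeration on a tied fixture", {
  # 6 subjects, one tie of size 2 at t = 2
  time <- c(1, 2, 2, 3, 4, 5)
  event <- c(1, 1, 1, 0, 1, 0)
  X <- matrix(c(0, 1, 0, 1, 1, 0, 0.5, -1, 2, 0, 1, -0.3), ncol = 2)
  for (beta in list(c(0, 0), c(0.5, -0.2), c(-1, 1), c(2, 0.3))) {
    ours <- cox_loglik(beta, time, event, X, ties = "exact")$loglik
    orc <- oracle_exact_loglik(beta, time, event, X)
    expect_equal(ours, orc, tolerance = 1e-9)
  }
})

test_that("exact and Breslow agree without ties; null covariates give HR ~ 1", {
  set.seed(9)
  t <- rexp(40, 0.1) + cumsum(rep(1e-4, 40))  # distinct times
  ev <- rbinom(40, 1, 0.8)
  x <- matrix(rbinom(40, 1, 0.5), ncol = 1, dimnames = list(NULL, "g"))
  fe <- cox_fit(t, ev, x, ties = "exact")
  fb <- cox_fit(t, ev, x, ties = "breslow")
  expect_equal(fe$loglik, fb$loglik, tolerance = 1e-6)
  expect_equal(fe$coefficients, fb$coefficients, tolerance = 1e-6)

  # covariate independent of outcome: CI spans 1
  set.seed(10)
  xperm <- matrix(sample(x), ncol = 1, dimnames = list(NULL, "g"))
  fp <- cox_fit(t, ev, xperm)
  expect_true(fp$ci_low[1] < 1 && 1 < fp$ci_high[1])
  expect_lt(abs(fp$coefficients[1]), 1)
})

test_that("cox_fit matches survival::coxph with exact ties", {
  skip_if_not_installed("survival")
  set.seed(12)
  n <- 70
  x <- cbind(a = rbinom(n, 1, 0.5), b = rnorm(n))
  t <- ceiling(rexp(n, exp(0.6 * x[, 1] - 0.4 * x[, 2]) * 0.08))
  ev <- rbinom(n, 1, 0.8)
  ours <- cox_fit(t, ev, x, ties = "exact")
  ref <- survival::coxph(survival::Surv(t, ev) ~ a + b,
                         data = data.frame(x), ties = "exact")
  expect_equal(unname(ours$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(ours$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-5)
  expect_true(ours$converged)
})

test_that("exact log-likelihood is concave along lines through the optimum", {
  set.seed(14)
  n <- 30
  x <- matrix(rbinom(n, 1, 0.5), ncol = 1)
  t <- ceiling(rexp(n, 0.1 * exp(0.8 * x[, 1])))
  ev <- rep(1, n)
  fit <- cox_fit(t, ev, x)
  b_hat <- fit$coefficients
  dirs <- c(-1, 1)
  for (dr in dirs) {
    lam <- seq(0, 2, length.out = 9)
    ll <- vapply(lam, function(l)
      cox_loglik(b_hat + dr * l, t, ev, sweep(x, 2, colMeans(x)),
                 "exact")$loglik, numeric(1))
    expect_true(all(diff(ll) <= 1e-10))  # non-increasing away from optimum
  }
})

test_that("degenerate Cox inputs error or flag rather than failing silently", {
  expect_error(cox_fit(c(1, 2, 3), c(0, 0, 0),
                       matrix(c(1, 0, 1), ncol = 1)), "no events")
  expect_error(cox_fit(c(1, 2, 3), c(1, 1, 0),
                       matrix(1, 3, 1)), "constant covariate")
  # perfect separation: all events in one arm, monotone likelihood
  t <- c(1, 2, 3, 10, 11, 12); ev <- c(1, 1, 1, 0, 0, 0)
  x <- matrix(c(1, 1, 1, 0, 0, 0), ncol = 1)
  fit <- cox_fit(t, ev, x)
  expect_true(fit$separation)
  expect_false(fit$converged)
})

test_that("rfs_table reports Klein tests when a group has no events", {
  time <- c(10, 20, 30, 40, 55, 60, 12, 18, 25, 33, 47, 60)
  event <- c(1, 1, 0, 1, 0, 0, rep(0, 6))
  grp <- rep(c("pos", "neg"), each = 6)
  tab <- rfs_table(time, event, grp, t0 = 50)
  expect_equal(nrow(tab$by_group), 2)
  pw <- tab$pairwise
  expect_true(is.na(pw$hr))
  expect_match(pw$hr_note, "zero events")
  expect_true(is.finite(pw$klein_z))
  # single group: no pairwise tests
  tab1 <- rfs_table(time[1:6], event[1:6], grp[1:6], t0 = 50)
  expect_null(tab1$pairwise)
})
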