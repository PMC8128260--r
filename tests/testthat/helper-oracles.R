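# Independent brute-force oracles used across tests. These deliberately do
# not share code with the package implementation.

# Product-limit estimate and Greenwood variance of log S, computed
# step-by-step from first principles.
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1 | event == TRUE]))
  s <- 1
  v <- 0
  out <- data.frame(time = ts, surv = NA_real_, var_log = NA_real_)
  for (k in seq_along(ts)) {
    n_k <- sum(time >= ts[k])
    d_k <- sum(time == ts[k] & (event == 1 | event == TRUE))
    s <- s * (1 - d_k / n_k)
    v <- v + if (n_k > d_k) d_k / (n_k * (n_k - d_k)) else Inf
    out$surv[k] <- s
    out$var_log[k] <- v
  }
  out
}

oracle_km_at <- function(time, event, t0) {
  tab <- oracle_km(time, event)
  keep <- tab$time <= t0
  if (!any(keep)) return(list(surv = 1, var_log = 0))
  k <- max(which(keep))
  list(surv = tab$surv[k], var_log = tab$var_log[k])
}

# Elementary symmetric polynomial by explicit subset enumeration.
oracle_esp <- function(w, d) {
  if (d == 0) return(1)
  sum(apply(combn(length(w), d), 2, function(idx) prod(w[idx])))
}

# Exact-ties Cox partial log-likelihood by enumeration.
oracle_exact_loglik <- function(beta, time, event, X) {
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[event == 1 | event == TRUE]))) {
    D <- which(time == t & (event == 1 | event == TRUE))
    R <- which(time >= t)
    ll <- ll + sum(eta[D]) - log(oracle_esp(w[R], length(D)))
  }
  ll
}

# Cochran-Armitage trend: hand-built from the score formulation.
oracle_ca_z <- function(x, n) {
  s <- seq_along(n) - 1
  N <- sum(n)
  p <- sum(x) / N
  num <- sum(x * s) - p * sum(n * s)
  den <- sqrt(p * (1 - p) * (sum(n * s^2) - sum(n * s)^2 / N))
  num / den
}

# Small deterministic survival fixture generator used by several tests.
fixture_surv <- function(seed, n, rate, cens = 60) {
  set.seed(seed)
  t_ev <- rexp(n, rate)
  time <- pmin(t_ev, cens)
  list(time = time, event = t_ev <= cens)
}
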