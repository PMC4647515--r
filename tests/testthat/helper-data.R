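# Shared fixtures, all generated in code.

# Small two-arm longitudinal dataset on the 6-step grid.
small_trial <- function(seed = 42, n = 30, or = 1.2, sigma_b = 0.5,
                        rho = 0.1, visits = c(0, 30, 60), mu0 = 0.25,
                        p0 = 0, p1 = 0, dropout = 0) {
  generate_trial(sim_config(
    n_patients = n, visit_times = visits,
    domains = list(list(domain = "PA", n_levels = 6L, mu0 = mu0, or = or,
                        rho = rho, sigma_b = sigma_b, p0 = p0, p1 = p1)),
    dropout_hazard = dropout, seed = seed))
}

# Hand-rolled trajectories for the TTD module: one row per visit.
traj <- function(id, arm, times, scores, domain = "CF") {
  data.frame(patient_id = id, arm = arm, visit_time = times,
             domain = domain, score = scores, stringsAsFactors = FALSE)
}

# Brute-force marginal likelihood for a single (k, n) observation:
# trapezoid integration of the BB pmf against the N(0, sigma^2) density.
trapezoid_marginal <- function(eta, sigma_b, rho, k, n, n_grid = 1e4) {
  b <- seq(-8 * max(sigma_b, 1e-3), 8 * max(sigma_b, 1e-3), length.out = n_grid)
  f <- bb_pmf(rep(k, n_grid), n, plogis(eta + b), rho) *
    stats::dnorm(b, 0, sigma_b)
  h <- diff(b)[1]
  sum((f[-1] + f[-n_grid]) / 2) * h
}

# Hand product-limit estimator (no ties handling beyond shared times).
brute_km <- function(time, event) {
  ut <- sort(unique(time[event]))
  S <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event)
    S <- S * (1 - d / at_risk)
    out$surv[i] <- S
  }
  out
}

brute_km_median <- function(time, event) {
  km <- brute_km(time, event)
  hit <- which(km$surv <= 0.5 + 1e-12)
  if (length(hit)) km$time[hit[1]] else NA_real_
}

# Cox partial likelihood (Breslow form is exact here when no tied events).
brute_cox_loglik <- function(beta, time, event, arm) {
  ll <- 0
  for (t in time[event]) {
    risk <- time >= t
    i <- which(time == t & event)
    ll <- ll + beta * arm[i] - log(sum(exp(beta * arm[risk])))
  }
  ll
}
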