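#' Configuration for the synthetic trial generator
#'
#' Defaults emulate a mid-sized randomized lung-cancer trial with monthly
#' HRQoL assessment: 150 patients per arm, five visits, a single
#' symptom-type domain whose scores are heavily skewed towards the good end
#' of the scale (baseline mean proportion 0.25), within-patient correlation
#' from a logit-scale random intercept (sd 0.5), Beta-Binomial
#' overdispersion 0.1, and 5% per-visit dropout.
#'
#' @param n_patients Patients per arm.
#' @param visit_times Assessment times (days from randomization).
#' @param domains List of per-domain settings; each element a list with
#'   `domain` (code), `n_levels`, `mu0` (baseline mean proportion),
#'   `or` (true subject-specific treatment odds ratio), `rho`
#'   (overdispersion in `[0,1)`), `sigma_b` (random-intercept sd), `p0`,
#'   `p1` (floor/ceiling inflation probabilities; when either is positive
#'   the domain is generated in continuous inflated-beta mode rather than on
#'   the count grid).
#' @param dropout_hazard Per-visit discrete dropout hazard; length 1 or 2
#'   (control, experimental).
#' @param informative_dropout Coupling of the dropout log-hazard-odds to the
#'   latent patient intercept (0 = missing at random given arm and time).
#' @param seed Mandatory RNG seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 150L,
                       visit_times = c(0, 30, 60, 90, 120),
                       domains = list(list(domain = "PA", n_levels = 6L,
                                           mu0 = 0.25, or = 1.2, rho = 0.1,
                                           sigma_b = 0.5, p0 = 0, p1 = 0)),
                       dropout_hazard = 0.05,
                       informative_dropout = 0,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  for (d in domains) {
    if (d$or <= 0) stop("true OR must be positive")
    if (d$p0 + d$p1 >= 1) stop("inflation probabilities must sum to < 1")
    if (d$rho < 0 || d$rho >= 1) stop("rho must lie in [0, 1)")
    if (d$mu0 <= 0 || d$mu0 >= 1) stop("mu0 must lie in (0, 1)")
  }
  if (any(dropout_hazard < 0 | dropout_hazard >= 1))
    stop("dropout hazard must lie in [0, 1)")
  structure(list(n_patients = as.integer(n_patients),
                 visit_times = visit_times, domains = domains,
                 dropout_hazard = rep(dropout_hazard, length.out = 2L),
                 informative_dropout = informative_dropout,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic QLQ-C30-like trial dataset
#'
#' Per patient a random intercept `b_i ~ N(0, sigma_b^2)` is drawn; per
#' visit the mean proportion is `mu = plogis(qlogis(mu0) + log(or) * trt +
#' b_i)`. In grid mode (no inflation) the score is `k/n * 100` with
#' `k ~ BetaBinomial(n_levels, mu, rho)`; in inflated mode the score is 0 or
#' 100 with probabilities `p0`, `p1`, otherwise a continuous
#' `Beta(mu * phi, (1 - mu) * phi)` draw with `phi = (1 - rho) / rho`.
#' Dropout removes all visits from the first "failed" assessment onwards via
#' a per-visit discrete hazard, optionally arm-dependent and optionally tied
#' to `b_i` (informative dropout). Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Trial dataset (score layout) with attribute `truth` recording the
#'   generating parameters.
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  vt <- config$visit_times
  arm <- rep(0:1, each = n)
  ids <- sprintf("P%04d", seq_len(2L * n))
  out <- vector("list", length(config$domains))
  for (j in seq_along(config$domains)) {
    d <- config$domains[[j]]
    b <- rnorm(2L * n, 0, d$sigma_b)
    # dropout: visit index from which the patient stops responding
    haz <- config$dropout_hazard[arm + 1L]
    if (config$informative_dropout != 0)
      haz <- plogis(qlogis(pmin(pmax(haz, 1e-6), 1 - 1e-6)) +
                    config$informative_dropout * b)
    nv <- length(vt)
    keep_until <- rep(nv, 2L * n)
    if (any(haz > 0) && nv > 1L) {
      u <- matrix(runif(2L * n * (nv - 1L)), 2L * n, nv - 1L)
      drop_at <- apply(u < haz, 1L, function(z) {
        w <- which(z); if (length(w)) w[1] + 1L else Inf
      })
      keep_until <- pmin(nv, drop_at - 1L)
    }
    rows <- lapply(seq_len(2L * n), function(i) {
      nvis <- keep_until[i]
      if (nvis < 1L) return(NULL)
      # baseline is assessed pre-treatment: the arm effect applies only to
      # post-baseline visits
      trt_on <- as.numeric(vt[seq_len(nvis)] > vt[1L]) * arm[i]
      mu <- plogis(qlogis(d$mu0) + log(d$or) * trt_on + b[i])
      if (d$p0 + d$p1 > 0) {
        cat3 <- sample.int(3L, nvis, replace = TRUE,
                           prob = c(d$p0, 1 - d$p0 - d$p1, d$p1))
        phi <- if (d$rho > 0) (1 - d$rho) / d$rho else 50
        s <- ifelse(cat3 == 1L, 0,
             ifelse(cat3 == 3L, 100,
                    100 * rbeta(nvis, mu * phi, (1 - mu) * phi)))
      } else {
        pvis <- rbeta(nvis, mu * (1 - d$rho) / max(d$rho, 1e-12),
                      (1 - mu) * (1 - d$rho) / max(d$rho, 1e-12))
        if (d$rho < 1e-8) pvis <- rep(mu, nvis)
        k <- rbinom(nvis, d$n_levels, pvis)
        s <- k / d$n_levels * 100
      }
      data.frame(patient_id = ids[i], arm = arm[i], visit_time = vt[seq_len(nvis)],
                 domain = d$domain, score = s, stringsAsFactors = FALSE)
    })
    out[[j]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  attr(res, "truth") <- config
  res
}

#' Configuration for the crossing-hazards deterioration generator
#'
#' @param n_patients Patients per arm.
#' @param visit_times Assessment times (default monthly for 24 months, in
#'   days).
#' @param changepoint Fraction of follow-up at which the arm hazard ratio for
#'   deterioration reverses (1 = no reversal).
#' @param hr_early Experimental-vs-control deterioration hazard ratio before
#'   the changepoint; after it the ratio is `1 / hr_early`.
#' @param base_hazard Per-visit control-arm deterioration hazard.
#' @param seed Mandatory RNG seed.
#' @return Object of class `crossing_config`.
#' @export
crossing_config <- function(n_patients = 150L,
                            visit_times = seq(0, 720, by = 30),
                            changepoint = 0.5, hr_early = 3,
                            base_hazard = 0.03, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(changepoint > 0, changepoint <= 1, hr_early > 0,
            base_hazard > 0, base_hazard < 1)
  structure(list(n_patients = as.integer(n_patients),
                 visit_times = visit_times, changepoint = changepoint,
                 hr_early = hr_early, base_hazard = base_hazard,
                 seed = as.integer(seed)),
            class = "crossing_config")
}

#' Generate trajectories whose deterioration hazards cross
#'
#' Simulates a function-type domain (baseline score 66.7 on the 6-step grid)
#' in which each patient's latent deterioration time follows a discrete
#' piecewise hazard: the experimental-vs-control hazard ratio is `hr_early`
#' before the changepoint visit and `1 / hr_early` after it, so an early
#' HRQoL benefit reverses late and the Kaplan-Meier curves cross. Scores
#' drop by two grid steps (33.3 points) at deterioration and stay low, so
#' [derive_td()] at any threshold up to 33 recovers the latent event times.
#' Patients who never deteriorate keep their baseline score (censored at the
#' last visit).
#'
#' @param config A [crossing_config()].
#' @return Trial dataset (score layout), domain `"CF"`.
#' @export
generate_crossing_hazards <- function(config) {
  stopifnot(inherits(config, "crossing_config"))
  set.seed(config$seed)
  n <- config$n_patients
  vt <- config$visit_times
  nv <- length(vt)
  cp <- ceiling(config$changepoint * (nv - 1L))
  arm <- rep(0:1, each = n)
  ids <- sprintf("P%04d", seq_len(2L * n))
  rows <- lapply(seq_len(2L * n), function(i) {
    hr <- ifelse(seq_len(nv - 1L) <= cp, config$hr_early, 1 / config$hr_early)
    haz <- pmin(config$base_hazard * if (arm[i] == 1L) hr else rep(1, nv - 1L), 0.95)
    u <- runif(nv - 1L)
    hit <- which(u < haz)
    det_vis <- if (length(hit)) hit[1] + 1L else NA_integer_
    s <- rep(200 / 3, nv)           # 66.7 on the 6-step grid
    if (!is.na(det_vis)) s[det_vis:nv] <- 100 / 3
    data.frame(patient_id = ids[i], arm = arm[i], visit_time = vt,
               domain = "CF", score = s, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  attr(res, "truth") <- config
  res
}
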