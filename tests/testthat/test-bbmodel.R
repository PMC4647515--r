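test_that("Beta-Binomial pmf normalizes over a parameter grid", {
  for (n in c(3L, 6L, 12L)) for (mu in c(0.1, 0.5, 0.9))
    for (rho in c(0, 0.05, 0.3, 0.8))
      expect_equal(sum(bb_pmf(0:n, n, mu, rho)), 1, tolerance = 1e-12)
})

test_that("pmf special cases: discrete uniform and the binomial limit", {
  # mu = 0.5, rho = 1/3 gives alpha = beta = 1: discrete uniform on 0..n
  expect_equal(bb_pmf(0:2, 2, 0.5, 1/3), rep(1/3, 3), tolerance = 1e-12)
  # rho -> 0 converges to Binomial(n, mu)
  expect_equal(bb_pmf(1, 2, 0.5, 1e-9), 0.5, tolerance = 1e-6)
  expect_equal(bb_pmf(0:6, 6, 0.3, 1e-10), dbinom(0:6, 6, 0.3),
               tolerance = 1e-6)
  expect_error(bb_pmf(3, 2, 0.5, 0.1), "k <= n")
  expect_error(bb_pmf(1, 2, 1.2, 0.1), "mu")
})

test_that("marginal likelihood: degenerate integral, backends, refinement", {
  d <- small_trial(seed = 11, n = 15)
  cnt <- to_counts(d$score, 6)
  X <- cbind(1, d$arm)
  beta <- c(-0.9, 0.15)
  # sigma_b = 0 collapses to the fixed-effects-only log-likelihood exactly
  ll0 <- bb_marginal_loglik(beta, 0, 0.1, cnt$k, cnt$n, X, d$patient_id)
  mu <- plogis(drop(X %*% beta))
  expect_equal(ll0, sum(bb_pmf(cnt$k, cnt$n, mu, 0.1, log = TRUE)),
               tolerance = 1e-10)
  # R and C++ backends agree
  ll_cpp <- bb_marginal_loglik(beta, 0.4, 0.1, cnt$k, cnt$n, X, d$patient_id)
  ll_r <- bb_marginal_loglik(beta, 0.4, 0.1, cnt$k, cnt$n, X, d$patient_id,
                             backend = "R")
  expect_equal(ll_cpp, ll_r, tolerance = 1e-10)
  # quadrature refinement: 15 vs 61 nodes
  ll61 <- bb_marginal_loglik(beta, 0.4, 0.1, cnt$k, cnt$n, X, d$patient_id,
                             nodes = 61)
  expect_lt(abs(ll_cpp - ll61), 1e-4)
})

test_that("marginal likelihood matches brute-force quadrature on single obs", {
  for (case in list(list(k = 2L, n = 6L, eta = -0.5, s = 0.7, rho = 0.15),
                    list(k = 0L, n = 6L, eta = 0.3, s = 1.2, rho = 0.05),
                    list(k = 6L, n = 6L, eta = 1.0, s = 0.4, rho = 0.4))) {
    ll <- bb_marginal_loglik(case$eta, case$s, case$rho, case$k, case$n,
                             matrix(1), "p1", nodes = 41)
    oracle <- log(trapezoid_marginal(case$eta, case$s, case$rho,
                                     case$k, case$n))
    expect_equal(ll, oracle, tolerance = 1e-6)
  }
})

test_that("fitted treatment OR is reciprocal under arm relabelling", {
  d <- small_trial(seed = 21, n = 40, or = 1.3)
  f1 <- fit_bb(d, spec = bb_spec(n_starts = 1))
  d2 <- d; d2$arm <- 1L - d2$arm
  f2 <- fit_bb(d2, spec = bb_spec(n_starts = 1))
  expect_true(f1$converged && f2$converged)
  expect_equal(f2$or$estimate, 1 / f1$or$estimate, tolerance = 1e-6)
})

test_that("boundary separation raises a diagnostic pointing to the inflated model", {
  d <- rbind(
    traj("a", 0L, c(0, 30), c(50, 50), "PA"),
    traj("b", 0L, c(0, 30), c(50, 33.3), "PA"),
    traj("c", 1L, c(0, 30), c(0, 0), "PA"),
    traj("d", 1L, c(0, 30), c(0, 0), "PA"))
  expect_error(fit_bb(d, n_levels = 6), "zero-one inflated")
})

test_that("single-arm or empty inputs are rejected", {
  d <- small_trial(seed = 3, n = 6)
  expect_error(fit_bb(d[d$arm == 0, ]), "both arms")
  expect_error(fit_bb(d[0, ]), "empty")
})
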