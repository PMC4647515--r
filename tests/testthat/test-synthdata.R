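test_that("generation is deterministic given the seed and validates configs", {
  cfg <- sim_config(n_patients = 20, seed = 123)
  expect_identical(generate_trial(cfg), generate_trial(cfg))
  expect_error(sim_config(seed = 1, domains = list(
    list(domain = "PA", n_levels = 6, mu0 = 0.3, or = -1, rho = 0.1,
         sigma_b = 0.3, p0 = 0, p1 = 0))), "OR must be positive")
  expect_error(sim_config(seed = 1, domains = list(
    list(domain = "PA", n_levels = 6, mu0 = 0.3, or = 1, rho = 0.1,
         sigma_b = 0.3, p0 = 0.6, p1 = 0.5))), "sum")
  expect_error(sim_config(n_patients = 10), "seed")
})

test_that("the null configuration leaves arm means equal", {
  d <- small_trial(seed = 20, n = 2000, or = 1, sigma_b = 0, rho = 1e-9,
                   visits = c(0, 30))
  m0 <- mean(d$score[d$arm == 0]); m1 <- mean(d$score[d$arm == 1])
  se <- sqrt(var(d$score[d$arm == 0]) / sum(d$arm == 0) +
             var(d$score[d$arm == 1]) / sum(d$arm == 1))
  expect_lt(abs(m1 - m0), 3 * max(se, 1e-6))
})

test_that("boundary inflation mass matches the configuration", {
  d <- small_trial(seed = 22, n = 300, p0 = 0.1, p1 = 0.25,
                   visits = c(0, 30, 60))
  expect_lt(abs(mean(d$score == 0 & d$arm == 0) / mean(d$arm == 0) - 0.1), 0.03)
  expect_lt(abs(mean(d$score == 100) - 0.25), 0.03)
})

test_that("within-patient correlation rises with the random-intercept sd", {
  icc <- vapply(c(0.1, 0.5, 1.2), function(s) {
    d <- small_trial(seed = 23, n = 200, sigma_b = s, visits = c(0, 30, 60))
    w <- reshape(d[c("patient_id", "visit_time", "score")],
                 idvar = "patient_id", timevar = "visit_time",
                 direction = "wide")
    cc <- cor(w[, -1], use = "pairwise.complete.obs")
    mean(cc[upper.tri(cc)])
  }, 0)
  expect_true(all(diff(icc) > 0))
})

test_that("dropout truncates follow-up monotonically over visits", {
  d <- small_trial(seed = 24, n = 400, visits = c(0, 30, 60, 90, 120),
                   dropout = 0.15)
  counts <- table(d$visit_time)
  expect_true(all(diff(as.integer(counts)) <= 0))
  expect_lt(counts[[5]], counts[[1]])
})

test_that("crossing-hazards trajectories cross and are seed-stable", {
  cfg <- crossing_config(n_patients = 50, seed = 25)
  expect_identical(generate_crossing_hazards(cfg),
                   generate_crossing_hazards(cfg))
  d <- generate_crossing_hazards(crossing_config(seed = 26))
  r <- derive_td(d, threshold = 5)
  # early: experimental deteriorates faster; late: control catches up
  early <- r[r$td_time <= 360 & r$event, ]
  expect_gt(mean(early$arm), 0.5)
})
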