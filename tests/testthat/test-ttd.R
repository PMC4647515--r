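cf_grid <- c(0, 16.7, 33.3, 50.0, 66.7, 83.3, 100)

test_that("deterioration events respect domain orientation and the grid", {
  # CF (function): baseline 50 dropping to 33.3 is a 16.7-point fall >= 5
  d <- traj("a", 0L, c(0, 30, 60), c(50, 50, 33.3))
  d <- rbind(d, traj("b", 1L, c(0, 30, 60), c(50, 50, 50)))
  r <- derive_td(d, threshold = 5)
  expect_true(r$event[r$patient_id == "a"])
  expect_equal(r$td_time[r$patient_id == "a"], 60)
  expect_false(r$event[r$patient_id == "b"])       # constant: censored
  expect_equal(r$td_time[r$patient_id == "b"], 60)
  # symptom domain deteriorates upwards
  s <- rbind(traj("a", 0L, c(0, 30), c(0, 16.7), "PA"),
             traj("b", 1L, c(0, 30), c(16.7, 0), "PA"))
  rs <- derive_td(s, threshold = 5)
  expect_true(rs$event[rs$patient_id == "a"])
  expect_false(rs$event[rs$patient_id == "b"])     # improvement is not an event
})

test_that("thresholds between achievable steps are equivalent; monotone in threshold", {
  d <- rbind(traj("a", 0L, c(0, 30), c(50, 33.3)),   # drop 16.7
             traj("b", 1L, c(0, 30), c(66.7, 66.7)))
  r16 <- derive_td(d, threshold = 16)
  expect_true(r16$event[r16$patient_id == "a"])      # 16.7 >= 16
  expect_error(derive_td(d, threshold = 17), "not estimable")  # 16.7 < 17
  # threshold monotonicity on simulated trajectories
  set.seed(14)
  dd <- generate_crossing_hazards(crossing_config(n_patients = 40, seed = 14))
  n_events <- vapply(c(5, 16, 33), function(th)
    sum(derive_td(dd, threshold = th)$event), 0)
  expect_true(all(diff(n_events) <= 0))
})

test_that("patients with no post-baseline visit are censored at zero", {
  d <- rbind(traj("a", 0L, 0, 50), traj("b", 1L, c(0, 30), c(50, 16.7)))
  expect_warning(r <- derive_td(d, threshold = 5), "censored at 0")
  expect_equal(r$td_time[r$patient_id == "a"], 0)
  expect_false(r$event[r$patient_id == "a"])
})

test_that("KM medians match the hand product-limit oracle", {
  r <- data.frame(patient_id = 1:4, arm = 0L, td_time = c(1, 2, 3, 4),
                  event = TRUE)
  expect_equal(unname(km_median(r)), 2)  # S(2) = 0.5 -> first time <= 0.5
  # all censored or a single late event: median undefined
  r2 <- data.frame(patient_id = 1:5, arm = 0L, td_time = 5:9, event = FALSE)
  expect_true(is.na(km_median(r2)))
  r3 <- data.frame(patient_id = 1:5, arm = 0L, td_time = c(5, 6, 7, 8, 9),
                   event = c(TRUE, rep(FALSE, 4)))
  expect_true(is.na(km_median(r3)))
  # randomized small datasets against the brute-force product limit
  set.seed(15)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    rr <- data.frame(patient_id = seq_len(n), arm = 0L,
                     td_time = sample(1:6, n, replace = TRUE),
                     event = runif(n) < 0.7)
    if (!any(rr$event)) next
    expect_equal(unname(km_median(rr)),
                 brute_km_median(rr$td_time, rr$event))
  }
})

test_that("Cox HR matches a brute-force partial-likelihood oracle", {
  # identical (mirrored) arms: HR = 1
  base <- data.frame(patient_id = 1:6, arm = 0L,
                     td_time = c(1, 2, 3, 4, 5, 6),
                     event = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
  mir <- base; mir$arm <- 1L; mir$patient_id <- 7:12
  f <- cox_hr(rbind(base, mir))
  expect_equal(f$hr, 1, tolerance = 1e-6)
  # arm-swap reciprocity
  d <- data.frame(patient_id = 1:8, arm = rep(0:1, 4),
                  td_time = c(1, 2, 3, 4, 5, 6, 7, 8),
                  event = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  f1 <- cox_hr(d)
  d2 <- d; d2$arm <- 1L - d2$arm
  expect_equal(cox_hr(d2)$hr, 1 / f1$hr, tolerance = 1e-6)
  # 2-per-arm toy with untied event times: hand-maximized partial likelihood
  toy <- data.frame(patient_id = 1:4, arm = c(0L, 0L, 1L, 1L),
                    td_time = c(2, 5, 1, 4), event = c(TRUE, TRUE, TRUE, FALSE))
  ft <- cox_hr(toy)
  o <- optimize(function(b) -brute_cox_loglik(b, toy$td_time, toy$event, toy$arm),
                c(-5, 5))
  expect_equal(log(ft$hr), o$minimum, tolerance = 1e-4)
  expect_error(cox_hr(data.frame(patient_id = 1:2, arm = 0:1,
                                 td_time = c(1, 2), event = FALSE)),
               "no events")
})

test_that("PH diagnostic is withheld below 3 events", {
  r <- data.frame(patient_id = 1:6, arm = rep(0:1, 3),
                  td_time = 1:6, event = c(TRUE, TRUE, rep(FALSE, 4)))
  expect_true(ph_diagnostic(r)$withheld)
})

test_that("PH diagnostic flags crossing hazards and passes proportional ones", {
  viol <- ok <- logical(12)
  for (r in seq_along(viol)) {
    dc <- generate_crossing_hazards(crossing_config(seed = 500 + r))
    viol[r] <- !ph_diagnostic(derive_td(dc, threshold = 5))$ph_ok
    dp <- generate_crossing_hazards(
      crossing_config(changepoint = 1, hr_early = 1.3, seed = 700 + r))
    ok[r] <- ph_diagnostic(derive_td(dp, threshold = 5))$ph_ok
  }
  expect_gte(mean(viol), 0.8)
  expect_gte(mean(ok), 0.75)  # small-sample screen; the full-size study
                              # lives in the acceptance suite
})
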