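test_that("domain definitions cover the instrument structure", {
  defs <- qlq_domains()
  expect_equal(nrow(defs), 15L)
  expect_equal(sum(defs$kind == "function"), 5L)
  expect_equal(sum(defs$kind == "symptom"), 9L)  # 8 symptom scales + FI
  expect_equal(sum(defs$kind == "global"), 1L)
  expect_true(all(defs$n_levels >= 3L))
  # every item 1..30 used exactly once
  items <- unlist(lapply(strsplit(defs$items, ","), as.integer))
  expect_equal(sort(items), 1:30)
  expect_equal(defs$n_levels[defs$domain == "CF"], 6L)
  expect_equal(defs$n_levels[defs$domain == "QL"], 12L)
})

test_that("domain scoring follows orientation and hand arithmetic", {
  expect_equal(score_domain(c(1, 1), "NV"), 0)        # symptom minimum
  expect_equal(score_domain(c(1, 1), "CF"), 100)      # function reverse-coded
  # PF example: RS = 1.4 -> (1 - 0.4/3) * 100
  expect_equal(score_domain(c(1, 2, 2, 1, 1), "PF"), (1 - 0.4 / 3) * 100)
  expect_equal(score_domain(c(7, 7), "QL"), 100)      # global best
  # permuting items leaves the score unchanged
  set.seed(1)
  for (r in 1:20) {
    it <- sample(1:4, 4, replace = TRUE)
    expect_equal(score_domain(it, "EF"), score_domain(sample(it), "EF"))
  }
})

test_that("missing items follow the half rule; bad responses are named", {
  expect_equal(score_domain(c(1, NA, 2, 1, 1), "PF"), (1 - 0.25 / 3) * 100)
  expect_true(is.na(score_domain(c(1, NA, NA, NA, 2), "PF")))   # 2 of 5 answered
  expect_false(is.na(score_domain(c(1, NA, NA, 2, 2), "PF")))   # 3 of 5 answered
  expect_true(is.na(score_domain(c(NA, NA), "NV")))
  expect_error(score_domain(c(5, 1), "NV"), "item 1")
  expect_error(score_domain(c(1, 2, 3), "NV"), "expects 2")
})

test_that("unit transform is the affine map with endpoint behaviour", {
  expect_identical(unit_transform(80), 0.8)
  expect_identical(unit_transform(0), 0)
  expect_identical(unit_transform(100), 1)
  s <- seq(0, 100, by = 12.5)
  expect_equal(unit_transform(s), s / 100)            # linear interpolation
  expect_error(unit_transform(101), "outside")
  expect_error(unit_transform(5, 10, 10), "minimum")
})

test_that("count representation round-trips every achievable grid score", {
  expect_equal(to_counts(66.7, 6)$k, 4L)
  expect_equal(to_counts(0, 12)$k, 0L)
  expect_equal(to_counts(100, 6)$k, 6L)
  for (n in c(3L, 6L, 9L, 12L, 15L)) {
    grid <- round(0:n / n * 100, 1)  # scores as printed to 1 dp
    cnt <- to_counts(grid, n)
    expect_equal(cnt$k, 0:n)
    expect_true(all(abs(cnt$k / n * 100 - grid) <= 0.05))
    # u and k/n agree to half a grid step
    expect_true(all(abs(cnt$k / n - unit_transform(grid)) <= 1 / (2 * n) + 1e-9))
  }
})

test_that("off-grid pre-computed scores warn but are kept", {
  expect_warning(check_grid(c(16.7, 42), "CF"), "off the 6-step grid")
  expect_silent(check_grid(c(0, 16.7, 33.3, 50, 66.7, 83.3, 100), "CF"))
})

test_that("scoring a full 30-item response yields all 15 domains", {
  resp <- c(rep(1, 28), 7, 7)  # best possible everywhere
  sc <- score_all_domains(resp)
  expect_equal(length(sc), 15L)
  defs <- qlq_domains()
  expect_equal(unname(sc[defs$domain[defs$kind != "symptom"]]),
               rep(100, 6))  # function + global at best = 100
  expect_equal(unname(sc[defs$domain[defs$kind == "symptom"]]), rep(0, 9))
})
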