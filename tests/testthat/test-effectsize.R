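test_that("mean-difference bands use |MD| with boundaries closed below", {
  expect_equal(as.character(classify_md(c(2.6096, 15.0773, -4.2, 12))),
               c("trivial", "large", "small", "medium"))
  expect_equal(as.character(classify_md(c(3, 10, 15))),
               c("trivial", "small", "medium"))  # boundary convention
  expect_equal(as.character(classify_md(c(3.0001, 10.0001, 15.0001))),
               c("small", "medium", "large"))
})

test_that("odds-ratio bands are additive around 1", {
  expect_equal(as.character(classify_or(c(1.16848, 1.0, 1.10396))),
               c("medium", "trivial", "medium"))
  expect_equal(as.character(classify_or(c(0.95, 1.05, 0.90, 1.10, 0.80, 1.20))),
               c("trivial", "trivial", "small", "small", "medium", "medium"))
  expect_equal(as.character(classify_or(c(0.7999, 1.2001))), c("large", "large"))
  # additive, not log-symmetric: both members of this reciprocal pair happen
  # to land in medium, but membership is defined additively
  expect_equal(as.character(classify_or(c(0.855, 1/0.855))), c("medium", "medium"))
  expect_error(classify_or(c(1.1, -2)), "positive")
})

test_that("bands are exhaustive and exclusive for any finite input", {
  set.seed(8)
  md <- runif(500, -40, 40)
  or <- exp(runif(500, -1, 1))
  expect_false(anyNA(classify_md(md)))
  expect_false(anyNA(classify_or(or)))
})

test_that("cross-tabulation conserves totals and respects alpha", {
  est <- data.frame(md = c(1, 5, 12, 20, -2), md_p = c(0.01, 0.2, 0.03, 0.6, 0.04),
                    or = c(1.01, 1.08, 1.15, 1.3, 0.85),
                    or_p = c(0.5, 0.04, 0.01, 0.001, 0.2))
  tab <- crosstab(est)
  expect_equal(sum(tab$md[, "all"]), 5L)
  expect_equal(sum(tab$or[, "all"]), 5L)
  expect_true(all(tab$md[, "significant"] <= tab$md[, "all"]))
  expect_equal(unname(tab$md[, "all"]), c(2L, 1L, 1L, 1L))
  expect_equal(unname(tab$md[, "significant"]), c(2L, 0L, 1L, 0L))
  expect_equal(unname(tab$or[, "significant"]), c(0L, 1L, 1L, 1L))
  # empty input gives an all-zero table
  tab0 <- crosstab(est[0, ])
  expect_equal(sum(tab0$md), 0L)
})

test_that("detection odds arithmetic matches the closed form", {
  expect_equal(detection_odds(0.24, 0.04), (0.24 / 0.76) / (0.04 / 0.96))
  expect_equal(detection_odds(0.5, 0.5), 1)
  expect_equal(detection_odds(c(10, 10, 5, 5), c(20, 0, 5, 5)), 1)  # equal props
  expect_equal(detection_odds(1, 0.3), Inf)
  expect_equal(detection_odds(0.3, 0), Inf)
})

test_that("equivalence mapping is identity on matched samples and monotone", {
  vals <- c(0.5, 1, 2, 2.5, 3.6, 5, 8, 12, 20)
  ors <- 1 + vals / 10                       # same magnitudes, OR > 1 scale
  m <- md_or_equivalence(vals, ors, md_grid = vals)
  expect_equal(m$or, ors, tolerance = 1e-10)  # identity under matched CDFs
  set.seed(9)
  mds <- rnorm(200, 0, 6); ors2 <- exp(rnorm(200, 0, 0.1))
  g <- sort(runif(20, 0.5, 12))
  m2 <- md_or_equivalence(mds, ors2, g)
  expect_true(all(diff(m2$or) >= -1e-12))     # monotone non-decreasing
  expect_warning(md_or_equivalence(c(1, 2), c(1.1, 1.2), 50), "clamped")
})
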