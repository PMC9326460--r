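test_that("attributable fractions combine multiplicatively", {
  expect_equal(multiplicativeCombinedPAF(c(0.1, 0.2)), 0.28, tolerance = 1e-12)
  expect_equal(multiplicativeCombinedPAF(0.37), 0.37)
  expect_equal(multiplicativeCombinedPAF(numeric(0)), 0)
  expect_error(multiplicativeCombinedPAF(c(0.5, 1)), "degenerate")

  for (seed in 1:50) {
    set.seed(seed)
    p <- runif(sample(1:6, 1), 0, 0.9)
    combined <- multiplicativeCombinedPAF(p)
    # order invariance
    expect_equal(multiplicativeCombinedPAF(sample(p)), combined,
                 tolerance = 1e-12)
    # subadditive for non-negative inputs, and still < 1
    expect_lte(combined, sum(p) + 1e-12)
    expect_lt(combined, 1)
  }
})

test_that("a null scenario changes nothing, exactly", {
  cv <- expCurve(t = 1, beta = 0.3, span = 10, component = "red_meat")
  burdens <- data.frame(outcome = "ihd", component_id = "red_meat",
                        daly_per_person_year = 0.02)
  baseline <- list(red_meat = intakeHistogram(c(0, 3), c(3, 8), c(0.4, 0.6)))
  d <- dietDelta(baseline, DietScenario("null", c(red_meat = 0)),
                 list(red_meat = cv), burdens)
  expect_identical(as.numeric(d), 0)
})

test_that("shifting a detrimental component upward increases the burden", {
  cv <- expCurve(t = 1, beta = 0.3, span = 20, component = "red_meat")
  burdens <- data.frame(outcome = "ihd", component_id = "red_meat",
                        daly_per_person_year = 0.02)
  baseline <- list(red_meat = intakePoint(5))
  d <- dietDelta(baseline, DietScenario("more", c(red_meat = 3)),
                 list(red_meat = cv), burdens)
  expect_gt(as.numeric(d), 0)
})

test_that("small shifts approach the marginal DRF limit with O(delta^2) error", {
  t <- 1; beta <- 0.3; x0 <- 4; B <- 0.02
  cv <- expCurve(t = t, beta = beta, span = 15, component = "sodium")
  burdens <- data.frame(outcome = "stroke", component_id = "sodium",
                        daly_per_person_year = B)
  baseline <- list(sodium = intakePoint(x0))
  drf <- as.numeric(marginalDRF(cv, intakePoint(x0), B, delta = 1e-4))

  relErr <- vapply(c(1, 0.1, 0.01), function(d) {
    delta <- as.numeric(dietDelta(baseline,
                                  DietScenario("s", c(sodium = d)),
                                  list(sodium = cv), burdens))
    abs(delta - drf * d * 365 / 1e6) / abs(drf * d * 365 / 1e6)
  }, numeric(1))
  expect_true(all(diff(relErr) < 0))         # error shrinks with delta
  expect_lt(relErr[2] / relErr[1], 0.15)     # ~order delta (one-sided diff)
  expect_lt(relErr[3], 1e-2)
})

test_that("components with disjoint outcomes contribute additively", {
  cvA <- expCurve(t = 1, beta = 0.3, span = 15, component = "red_meat")
  cvB <- expCurve(t = 0.5, beta = 0.2, span = 15, component = "sodium")
  curves <- list(red_meat = cvA, sodium = cvB)
  burdens <- data.frame(outcome = c("crc", "stroke"),
                        component_id = c("red_meat", "sodium"),
                        daly_per_person_year = c(0.01, 0.03))
  baseline <- list(red_meat = intakePoint(4), sodium = intakePoint(3))
  both <- dietDelta(baseline,
                    DietScenario("both", c(red_meat = 2, sodium = 1)),
                    curves, burdens)
  onlyA <- dietDelta(baseline, DietScenario("a", c(red_meat = 2)),
                     curves, burdens)
  onlyB <- dietDelta(baseline, DietScenario("b", c(sodium = 1)),
                     curves, burdens)
  expect_equal(as.numeric(both), as.numeric(onlyA) + as.numeric(onlyB),
               tolerance = 1e-12)
  # shared outcome would not be additive: combined multiplicatively instead
  shared <- data.frame(outcome = "ihd", component_id = c("red_meat", "sodium"),
                       daly_per_person_year = 0.02)
  bothShared <- dietDelta(baseline,
                          DietScenario("both", c(red_meat = 2, sodium = 1)),
                          curves, shared)
  expect_true(is.finite(as.numeric(bothShared)))
})

test_that("scenario validation rejects missing curves or burdens", {
  cv <- expCurve(component = "sodium")
  burdens <- data.frame(outcome = "stroke", component_id = "sodium",
                        daly_per_person_year = 0.02)
  baseline <- list(sodium = intakePoint(4))
  expect_error(dietDelta(baseline, DietScenario("s", c(fruits = 1)),
                         list(sodium = cv), burdens),
               "without a relative-risk curve")
  expect_error(dietDelta(baseline, DietScenario("s", c(fruits = 1)),
                         list(sodium = cv, fruits = cv), burdens),
               "without a burden set")
  expect_error(DietScenario("s", c(unregistered = 1)), "unknown component")
})

test_that("active-range fraction reports mass outside the TMREL", {
  tm <- TMRELRange(10, Inf)
  expect_identical(activeRangeFraction(intakePoint(15), tm), 0)
  expect_identical(activeRangeFraction(intakePoint(5), tm), 1)
  # uniform on [0, 2 low] with TMREL [low, Inf): half the mass is active
  expect_equal(activeRangeFraction(intakeHistogram(0, 20, 1), tm), 0.5,
               tolerance = 1e-12)
  # lognormal: closed form against plnorm
  d <- intakeLognormal(2, 0.4)
  expect_equal(activeRangeFraction(d, TMRELRange(5, 12)),
               plnorm(5, 2, 0.4) + 1 - plnorm(12, 2, 0.4), tolerance = 1e-12)
})
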