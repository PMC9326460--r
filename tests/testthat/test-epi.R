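test_that("relative-risk evaluation clamps inside the TMREL and interpolates log-linearly", {
  # two-knot curve (t, 1) -- (t + 1/beta, e): log-linear gives e at the far knot
  t <- 2; beta <- 0.5
  cv <- RRCurve("sodium", intake = c(t, t + 1 / beta), rr = c(1, exp(1)),
                tmrel = TMRELRange(0, t))
  expect_equal(rrEvaluate(cv, t + 1 / beta), exp(1), tolerance = 1e-12)
  # halfway in log space
  expect_equal(rrEvaluate(cv, t + 0.5 / beta), exp(0.5), tolerance = 1e-12)
  # inside the TMREL range: exactly 1
  expect_identical(rrEvaluate(cv, c(0, 1, t)), c(1, 1, 1))
  # constant extrapolation beyond the last knot
  expect_equal(rrEvaluate(cv, 100), exp(1), tolerance = 1e-12)
  expect_error(rrEvaluate(cv, -1), "non-negative")
})

test_that("malformed curves are rejected at construction", {
  expect_error(RRCurve("x", c(2, 1), c(1, 2)), "increasing")
  expect_error(RRCurve("x", c(1, 2), c(1, -2)), "positive")
  expect_error(RRCurve("x", c(1, 2), c(1, 2), TMRELRange(3, 1)), "low")
})

test_that("PAF matches closed forms", {
  # RR identically 1 -> PAF 0
  flat <- RRCurve("x", c(0, 10), c(1, 1))
  expect_equal(paf(flat, intakePoint(4)), 0)
  expect_equal(paf(flat, intakeHistogram(c(0, 5), c(5, 10), c(0.5, 0.5))), 0)

  # point mass with RR = 2 -> (2-1)/2 = 0.5
  cv <- RRCurve("red_meat", c(0, 50), c(1, 2), TMRELRange(0, 0))
  expect_equal(paf(cv, intakePoint(50)), 0.5, tolerance = 1e-12)

  # insufficient intake of a beneficial component: RR > 1 below the TMREL
  prot <- RRCurve("fruits", c(0, 100), c(2, 1), TMRELRange(100, Inf))
  expect_equal(paf(prot, intakePoint(0)), 0.5, tolerance = 1e-12)
  # intakes protective relative to the counterfactual give a negative PAF
  below <- RRCurve("x", c(0, 10), c(0.5, 0.5), TMRELRange(-2, -1))
  expect_equal(paf(below, intakePoint(5)), -1, tolerance = 1e-12)
})

test_that("histogram E[RR] agrees with a Monte Carlo oracle", {
  cv <- expCurve(t = 1, beta = 0.25, span = 12)
  dist <- intakeHistogram(lower = c(0, 2, 5), upper = c(2, 5, 9),
                          prob = c(0.3, 0.5, 0.2))
  got <- expectedRR(cv, dist)

  set.seed(42)
  n <- 1e6L
  bin <- sample.int(3L, n, replace = TRUE, prob = c(0.3, 0.5, 0.2))
  x <- runif(n, c(0, 2, 5)[bin], c(2, 5, 9)[bin])
  rr <- rrEvaluate(cv, x)
  se <- sd(rr) / sqrt(n)
  expect_lt(abs(got - mean(rr)), 3 * se)
})

test_that("lognormal E[RR] agrees with a Monte Carlo oracle", {
  cv <- expCurve(t = 1, beta = 0.2, span = 15)
  dist <- intakeLognormal(meanlog = 1, sdlog = 0.5)
  got <- expectedRR(cv, dist)
  set.seed(43)
  x <- rlnorm(1e6L, 1, 0.5)
  rr <- rrEvaluate(cv, x)
  expect_lt(abs(got - mean(rr)), 3 * sd(rr) / sqrt(length(rr)))
})

test_that("PAF is invariant under histogram bin refinement", {
  cv <- expCurve(t = 1, beta = 0.25, span = 12)
  coarse <- intakeHistogram(c(0, 4), c(4, 8), c(0.6, 0.4))
  fine <- intakeHistogram(c(0, 2, 4, 6), c(2, 4, 6, 8),
                          c(0.3, 0.3, 0.2, 0.2))
  expect_lt(abs(paf(cv, coarse) - paf(cv, fine)), 1e-12)
})

test_that("marginal DRF matches the analytic derivative for a point mass", {
  # above a TMREL [0, t], RR = exp(beta (x - t)), so PAF(x) = 1 - exp(-beta (x - t))
  # and d(AB)/dx = beta exp(-beta (x - t)) B; DRF = that / 365 * 1e6
  t <- 1; beta <- 0.3; x0 <- 3; B <- 0.02
  cv <- expCurve(t = t, beta = beta, span = 10)
  analytic <- beta * exp(-beta * (x0 - t)) * B / 365 * 1e6
  got <- marginalDRF(cv, intakePoint(x0), burden_rates = B, delta = 1e-3)
  expect_lt(abs(got - analytic) / analytic, 1e-4)
  expect_false(attr(got, "clamped"))
})

test_that("marginal DRF converges as O(delta^2) and respects sign and TMREL", {
  t <- 1; beta <- 0.3; x0 <- 3; B <- 0.02
  cv <- expCurve(t = t, beta = beta, span = 10)
  analytic <- beta * exp(-beta * (x0 - t)) * B / 365 * 1e6
  errs <- vapply(c(0.4, 0.2, 0.1), function(d)
    abs(as.numeric(marginalDRF(cv, intakePoint(x0), B, delta = d)) - analytic),
    numeric(1))
  # halving delta shrinks the error by about 4 (second order); allow slack
  expect_lt(errs[2] / errs[1], 0.30)
  expect_lt(errs[3] / errs[2], 0.30)

  # RR identically 1 -> DRF 0
  flat <- RRCurve("x", c(0, 10), c(1, 1))
  expect_equal(as.numeric(marginalDRF(flat, intakePoint(4), B)), 0)

  # support strictly inside the TMREL with margin > delta -> 0
  wide <- RRCurve("x", c(0, 20), c(1, 3), TMRELRange(0, 10))
  expect_equal(as.numeric(marginalDRF(wide, intakePoint(5), B, delta = 1)), 0)

  # detrimental curve (RR increasing) -> DRF >= 0; beneficial -> <= 0
  expect_gte(as.numeric(marginalDRF(cv, intakePoint(x0), B)), 0)
  benef <- RRCurve("fruits", c(0, 10), c(2, 1), TMRELRange(10, Inf))
  expect_lte(as.numeric(marginalDRF(benef, intakePoint(5), B)), 0)

  expect_error(marginalDRF(cv, intakePoint(3), B, delta = 0), "positive")
  expect_warning(marginalDRF(cv, intakePoint(0.5), B, delta = 1), "clamped")
})

test_that("stratified DRFs aggregate as a population-weighted mean", {
  expect_equal(aggregateStrata(c(a = 2, b = 4), c(a = 0.5, b = 0.5)), 3)
  expect_equal(aggregateStrata(c(a = 7), c(a = 1)), 7)
  expect_equal(aggregateStrata(c(a = 0, b = 8), c(a = 0.25, b = 0.75)), 6)
  expect_error(aggregateStrata(c(a = 1, b = 2), c(a = 1)), "weight")
  expect_error(aggregateStrata(c(a = 1), c(a = 0.5)), "sum to 1")

  # bounded between stratum extremes
  for (seed in 1:20) {
    set.seed(seed)
    d <- setNames(rnorm(4), letters[1:4])
    w <- runif(4); w <- setNames(w / sum(w), letters[1:4])
    agg <- aggregateStrata(d, w)
    expect_gte(agg, min(d)); expect_lte(agg, max(d))
  }
})
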