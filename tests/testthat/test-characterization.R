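test_that("characterization multiplies amounts by DRFs and sums", {
  fx <- yogurtFixture()
  res <- dietaryImpact(resolveComponents(fx$recipe), fx$drf)
  expect_lt(abs(totalUDALY(res) - (-0.9251)), 1e-9)
  expect_equal(perComponentUDALY(res)[["sodium"]], 0.114 * 13.90,
               tolerance = 1e-12)  # +1.585 uDALY

  zero <- dietaryImpact(RiskComponentVector(basis = "serving"), fx$drf)
  expect_identical(totalUDALY(zero), 0)
  expect_length(perComponentUDALY(zero), 0L)

  only_na <- dietaryImpact(RiskComponentVector(c(sodium = 0.114), "serving"),
                           fx$drf)
  expect_equal(totalUDALY(only_na), 1.5846, tolerance = 1e-12)
})

test_that("minute conversion is the exact linear map -0.526 per microDALY", {
  expect_equal(heniMinutes(-0.925), 0.526 * 0.925)
  expect_equal(round(heniMinutes(-0.925), 1), 0.5)
  expect_identical(heniMinutes(0), 0)
  expect_equal(heniMinutes(1), -0.526)
  expect_error(heniMinutes(Inf), "finite")

  # two computation paths agree: result slot vs sum of per-component minutes
  fx <- yogurtFixture()
  res <- dietaryImpact(resolveComponents(fx$recipe), fx$drf)
  expect_equal(heniMinutes(res), sum(perComponentMinutes(res)),
               tolerance = 1e-12)
  expect_equal(heniMinutes(res), heniMinutes(totalUDALY(res)),
               tolerance = 1e-12)
})

test_that("uncharacterized components are surfaced, not dropped or summed", {
  drf <- DRFTable(c(sodium = 13.90))
  vec <- RiskComponentVector(c(sodium = 0.1, fruits = 5), "serving")
  res <- dietaryImpact(vec, drf)
  expect_identical(uncharacterized(res), "fruits")
  expect_equal(totalUDALY(res), 0.1 * 13.90)
  expect_false("fruits" %in% names(perComponentUDALY(res)))
})

test_that("basis mismatch and non-finite DRFs are rejected", {
  fx <- yogurtFixture()
  vec <- resolveComponents(fx$recipe)
  expect_error(dietaryImpact(vec, fx$drf, reporting_basis = "per100g"),
               "basis mismatch")
  expect_error(DRFTable(c(sodium = Inf)), "finite")
})

test_that("contribution split conserves the total and signs the directions", {
  fx <- yogurtFixture()
  res <- dietaryImpact(resolveComponents(fx$recipe), fx$drf)
  sp <- contributionSplit(res)
  # detrimental ~0.90 min: sodium 0.83 + trans fat 0.07 on the uDALY-sign scale
  expect_lt(abs(sp$detrimental_minutes - 0.90), 0.01)
  expect_equal(sp$beneficial_minutes - sp$detrimental_minutes,
               heniMinutes(res), tolerance = 1e-12)
  expect_setequal(
    sp$table$component[sp$table$direction == "detrimental"],
    c("sodium", "tfa"))

  # all-beneficial vector has zero detrimental minutes
  allb <- dietaryImpact(RiskComponentVector(c(fruits = 3), "serving"), fx$drf)
  expect_identical(contributionSplit(allb)$detrimental_minutes, 0)

  # conservation holds for random vectors
  for (seed in 1:50) {
    g <- randomVectorAndDRF(seed)
    sp <- contributionSplit(dietaryImpact(g$vec, g$drf))
    expect_equal(sp$beneficial_minutes - sp$detrimental_minutes,
                 heniMinutes(dietaryImpact(g$vec, g$drf)), tolerance = 1e-12)
  }
})

test_that("impact is linear, monotone, and scale-equivariant", {
  for (seed in 1:25) {
    g <- randomVectorAndDRF(seed)
    a <- amounts(g$vec)
    b <- a * runif(length(a))
    vA <- RiskComponentVector(a, "serving")
    vB <- RiskComponentVector(b, "serving")
    vAB <- RiskComponentVector(a + b, "serving")
    expect_equal(totalUDALY(dietaryImpact(vAB, g$drf)),
                 totalUDALY(dietaryImpact(vA, g$drf)) +
                   totalUDALY(dietaryImpact(vB, g$drf)),
                 tolerance = 1e-12)
    expect_equal(perComponentUDALY(dietaryImpact(vAB, g$drf)),
                 perComponentUDALY(dietaryImpact(vA, g$drf)) +
                   perComponentUDALY(dietaryImpact(vB, g$drf)),
                 tolerance = 1e-12)

    # monotonicity in a single component
    cid <- names(a)[1L]
    bump <- a; bump[cid] <- bump[cid] + 1
    dTot <- totalUDALY(dietaryImpact(RiskComponentVector(bump, "serving"), g$drf)) -
      totalUDALY(dietaryImpact(vA, g$drf))
    if (drfEntries(g$drf)[[cid]] >= 0) expect_gte(dTot, 0) else expect_lte(dTot, 0)

    # converting serving -> per100g scales every impact by 100/mass
    mass <- 250
    v100 <- convertFunctionalUnit(vA, "per100g", serving_mass = mass)
    expect_equal(totalUDALY(dietaryImpact(v100, g$drf)),
                 totalUDALY(dietaryImpact(vA, g$drf)) * 100 / mass,
                 tolerance = 1e-12)
  }
})

test_that("dietary and environmental damages combine at damage level", {
  fx <- yogurtFixture()
  res <- dietaryImpact(resolveComponents(fx$recipe), fx$drf)
  comb <- combineWithEnvironmental(
    res, data.frame(label = "fine_particulate", udaly_per_fu = 0.05))
  expect_equal(comb$total_udaly, totalUDALY(res) + 0.05, tolerance = 1e-12)
  expect_setequal(comb$contributions$label, c("dietary", "fine_particulate"))
  expect_equal(sum(comb$contributions$abs_share), 1, tolerance = 1e-9)

  # empty environmental list: combined equals dietary
  alone <- combineWithEnvironmental(res)
  expect_equal(alone$total_udaly, totalUDALY(res))

  expect_error(
    combineWithEnvironmental(res, environmental_basis = "per100g"),
    "mixed")
  expect_error(
    combineWithEnvironmental(res, data.frame(label = c("a", "a"),
                                             udaly_per_fu = c(1, 2))),
    "duplicate")
})
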