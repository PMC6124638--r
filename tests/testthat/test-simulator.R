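test_that("genotypes follow Hardy-Weinberg category frequencies", {
  expect_error(simulateGenotypes(10, 2, 1.2), "maf")
  set.seed(1)
  G <- simulateGenotypes(1e5, 1, 0.3)
  expect_true(all(G %in% 0:2))
  pExp <- c(0.49, 0.42, 0.09)
  counts <- tabulate(G + 1L, nbins = 3)
  se <- sqrt(pExp * (1 - pExp) / 1e5)
  expect_true(all(abs(counts / 1e5 - pExp) < 3 * se))
  expect_equal(mean(G), 0.6, tolerance = 0.01)
  ## tiny maf: overwhelmingly zeros
  set.seed(2)
  expect_gt(mean(simulateGenotypes(1e4, 1, 1e-4) == 0), 0.999)
})

test_that("cohort structural equations collapse correctly in limits", {
  ## no pleiotropy, no SNP-confounder path, theta 0: Y independent of G
  ## except through nothing -> per-SNP outcome effects centre on 0
  cfg <- MRScenario(n = 5000, J = 10, theta = 0, q = 0,
                    omega1Range = c(0, 0), seed = 3)
  cohort <- simulateCohort(cfg)
  fits <- pleioMR:::marginalRegressions(cohort$genotypes, cohort$outcome)
  expect_lt(abs(mean(fits$slope)), 0.05)
  expect_equal(cohort$truePhi, rep(0, 10))
  ## deterministic limit: theta 1, no confounding, zero noise -> Y = X
  cfgD <- MRScenario(n = 50, J = 3, theta = 1, q = 0,
                     omega1Range = c(0, 0), omega2 = 0, omega3 = 0,
                     noise = 0, seed = 4)
  cohortD <- simulateCohort(cfgD)
  expect_equal(cohortD$outcome, cohortD$exposure)
})

test_that("marginal regressions equal the lm() closed form", {
  set.seed(11)
  G <- simulateGenotypes(60, 4, 0.3)
  y <- rnorm(60, mean = G %*% runif(4))
  fits <- pleioMR:::marginalRegressions(G, y)
  for (j in 1:4) {
    ref <- summary(lm(y ~ G[, j]))$coefficients
    expect_equal(fits$slope[j], ref[2, 1])
    expect_equal(fits$se[j], ref[2, 2])
  }
})

test_that("two-sample generation shares parameters across cohorts", {
  cfg <- scenarioPreset("II", theta = 0.05, n = 400, J = 8, seed = 21)
  d <- makeTwoSample(cfg, returnTruth = TRUE)
  truth <- attr(d, "truth")
  expect_equal(nInstruments(d), 8)
  expect_length(truth$alpha, 8)
  ## identical seed reproduces bit-identical output
  d2 <- makeTwoSample(cfg, returnTruth = TRUE)
  expect_identical(as.data.frame(d), as.data.frame(d2))
  expect_identical(attr(d2, "truth"), truth)
  ## zero-noise deterministic limit: within one cohort Y = theta * X,
  ## so marginal outcome slopes are exactly theta times the exposure
  ## slopes and every ratio equals theta
  cfgD <- MRScenario(n = 200, J = 5, theta = 0.4, q = 0,
                     omega2 = 0, omega3 = 0, noise = 0, seed = 5)
  cohort <- simulateCohort(cfgD)
  fx <- pleioMR:::marginalRegressions(cohort$genotypes, cohort$exposure)
  fy <- pleioMR:::marginalRegressions(cohort$genotypes, cohort$outcome)
  expect_equal(fy$slope / fx$slope, rep(0.4, 5), tolerance = 1e-10)
  ## across the two independent cohorts the identity holds only in
  ## expectation (other SNPs act as residual noise in each marginal fit)
  cfgD@n <- 5000L
  dd <- makeTwoSample(cfgD)
  expect_equal(betaHat(dd) / alphaHat(dd), rep(0.4, 5), tolerance = 0.1)
})

test_that("exposure effects are recovered at large n", {
  cfg <- scenarioPreset("I", n = 1e4, J = 20, seed = 31)
  d <- makeTwoSample(cfg, returnTruth = TRUE)
  truth <- attr(d, "truth")
  z <- (alphaHat(d) - truth$alpha) / seAlpha(d)
  expect_gte(mean(abs(z) < 3), 0.95)
  expect_lt(abs(mean(alphaHat(d) - truth$alpha)), 0.05)
})

test_that("scenario presets encode the study design", {
  p1 <- scenarioPreset("I")
  expect_equal(p1@phiRange, c(0, 0))
  expect_equal(p1@omega1Range, c(0, 0))
  expect_equal(p1@n, 1000L)
  expect_equal(p1@J, 20L)
  expect_equal(p1@maf, 0.30)
  expect_equal(p1@alphaRange, c(0.5, 4))

  p2 <- scenarioPreset("II", theta = 0.05)
  expect_equal(p2@phiRange, c(0, 0.2))
  expect_equal(p2@q, 1)
  expect_equal(p2@theta, 0.05)

  p3 <- scenarioPreset("III")
  expect_equal(p3@omega1Range, c(0, 0.5))

  ## mean pleiotropy E(phi) * q = 0.25 q; q = 0.4 gives 0.100
  p4 <- scenarioPreset("IV", q = 0.4)
  expect_equal(mean(p4@phiRange) * p4@q, 0.100)
  expect_equal(mean(scenarioPreset("IV", q = 0.1)@phiRange) * 0.1, 0.025)
  expect_equal(p4@omega1Range, c(0, 0))

  p5 <- scenarioPreset("V", L = -1.0, U = 1.0)
  expect_equal(p5@omega1Range, c(-1.0, 1.0))
  expect_equal(p5@q, 0.4)

  expect_error(scenarioPreset("VI"), "unknown scenario")
  ## invalid configurations are rejected
  expect_error(MRScenario(maf = 0.6), "maf")
  expect_error(MRScenario(q = 1.5), "q")
  expect_error(MRScenario(alphaRange = c(4, 0.5)), "ordered")
})

test_that("pleiotropy indicators couple phi and omega1 per SNP", {
  cfg <- scenarioPreset("V", q = 0.4, L = 0.2, U = 0.5,
                        phiRange = c(0.1, 0.5), n = 50, seed = 61)
  d <- makeTwoSample(cfg, returnTruth = TRUE)
  truth <- attr(d, "truth")
  ## the same SNPs carry pleiotropy and the confounder path
  expect_identical(truth$phi > 0, truth$omega1 > 0)
  expect_true(any(truth$phi == 0) || any(truth$phi > 0))
})

test_that("scenario configurations round-trip through YAML", {
  cfg <- scenarioPreset("V", theta = 0.05, q = 0.3, L = -0.6, U = 0.6,
                        seed = 9)
  f <- withr::local_tempfile(fileext = ".yaml")
  writeScenario(cfg, f)
  back <- readScenario(f)
  for (s in slotNames("MRScenario")) {
    expect_equal(slot(back, s), slot(cfg, s), label = s)
  }
})
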