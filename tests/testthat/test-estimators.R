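test_that("residual dispersion follows the clamped (1/(J-k)) rule", {
  ## perfect fit: zero dispersion, clamped to 1
  a <- c(1, 2, 3)
  sc <- pleioMR:::residualScale(cbind(a), 0.5 * a, diag(3), 0.5, k = 1)
  expect_equal(sc$sigma2Hat, 0)
  expect_equal(sc$sigma2Used, 1)
  ## unit weights, residuals (2,2,2), J=3, k=1: 12/2 = 6
  sc2 <- pleioMR:::residualScale(cbind(a), 0.5 * a + 2, diag(3), 0.5, k = 1)
  expect_equal(sc2$sigma2Hat, 6)
  expect_equal(sc2$sigma2Used, 6)
  ## brute-force recomputation on a random weighted instance
  set.seed(40)
  J <- 20
  X <- cbind(1, runif(J))
  y <- rnorm(J)
  se <- runif(J, 0.5, 2)
  cf <- c(0.2, 0.7)
  sc3 <- pleioMR:::residualScale(X, y, diag(se^2), cf, k = 2)
  eps <- (y - X %*% cf) / se
  expect_equal(sc3$sigma2Hat, sum(eps^2) / (J - 2))
  expect_error(
    pleioMR:::residualScale(cbind(a), a, diag(3), 1, k = 3),
    "insufficient instruments"
  )
})

test_that("IVW reproduces the exact-fit case and errors on J < 2", {
  d <- MRSummary(alpha = c(1, 2), seAlpha = c(0, 0),
                 beta = c(0.5, 1.0), seBeta = c(1, 1))
  f <- fitIVW(d)
  expect_equal(slope(f), 0.5)
  expect_equal(f@sigma2Hat, 0)
  expect_equal(f@sigma2Used, 1)
  expect_equal(slopeScale(f), sqrt(1 / 5))
  expect_true(all(is.na(intercept(f))))
  expect_equal(slopeInterval(f), 0.5 + c(-1, 1) * qnorm(0.975) * sqrt(1 / 5))
  expect_false(rejectSlope(f))
  d1 <- MRSummary(alpha = 1, seAlpha = 0, beta = 1, seBeta = 1)
  expect_error(fitIVW(d1), "at least 2")
})

test_that("MR-Egger recovers an exact linear relation and errors on J < 3", {
  a <- c(0.6, 1.3, 2.1, 3.5)
  d <- MRSummary(alpha = a, seAlpha = rep(0.1, 4),
                 beta = 0.3 + 0.7 * a, seBeta = rep(0.8, 4))
  f <- fitMREgger(d)
  expect_equal(intercept(f), 0.3)
  expect_equal(slope(f), 0.7)
  expect_equal(f@sigma2Hat, 0, tolerance = 1e-12)
  expect_error(fitMREgger(MRSummary(alpha = c(1, 2), seAlpha = c(0, 0),
                                    beta = c(1, 2), seBeta = c(1, 1))),
               "at least 3")
  ## collinear design: identical exposure effects
  dc <- MRSummary(alpha = rep(2, 4), seAlpha = rep(0, 4),
                  beta = 1:4, seBeta = rep(1, 4))
  expect_error(fitMREgger(dc), "collinear")
})

test_that("IVW and MR-Egger match the whitened-lm GLS oracle", {
  for (seed in 1:20) {
    J <- sample(4:25, 1)
    corr <- if (seed %% 4 == 0) randomCorr(J, seed + 100) else NULL
    d <- randomSummary(J, seed = seed, corr = corr)
    fI <- fitIVW(d)
    oI <- oracleGLS(d, withIntercept = FALSE)
    expect_sigdigits(slope(fI), oI$coef[1])
    expect_sigdigits(slopeScale(fI), oI$scales[1])
    expect_sigdigits(fI@sigma2Hat, oI$sigma2Hat)
    fE <- fitMREgger(d)
    oE <- oracleGLS(d, withIntercept = TRUE)
    expect_sigdigits(c(intercept(fE), slope(fE)), oE$coef)
    expect_sigdigits(c(interceptScale(fE), slopeScale(fE)), oE$scales)
  }
})

test_that("BMRE matches the augmented-data ridge oracle and its limits", {
  for (seed in 1:10) {
    J <- sample(3:25, 1)
    d <- randomSummary(J, seed = seed + 50)
    prior <- MRPrior(muPhi = 0.05, varPhi = 10^runif(1, -4, 1),
                     muTheta = 0.1, varTheta = 10^runif(1, -2, 2))
    f <- fitBayesMREgger(d, prior)
    expect_sigdigits(c(intercept(f), slope(f)), oracleRidge(d, prior))
    ## vague prior recovers MR-Egger
    fV <- fitBayesMREgger(d, MRPrior(varPhi = 1e6, varTheta = 1e6))
    fE <- fitMREgger(d)
    expect_equal(slope(fV), slope(fE), tolerance = 1e-3)
    expect_equal(intercept(fV), intercept(fE), tolerance = 1e-3)
    ## tight zero-mean intercept prior recovers IVW
    fT <- fitBayesMREgger(d, MRPrior(muPhi = 0, varPhi = 1e-12,
                                     varTheta = 1e6))
    expect_equal(slope(fT), slope(fitIVW(d)), tolerance = 1e-3)
  }
  expect_error(MRPrior(varPhi = -1), "varPhi")
  expect_error(fitBayesMREgger(randomSummary(5, 1),
                               MRPrior(varPhi = NA_real_)),
               "finite")
})

test_that("weighted median interpolates the weighted percentiles", {
  ## proportional effects: every ratio equals 0.7
  a <- c(0.5, 1, 2, 4)
  d <- MRSummary(alpha = a, seAlpha = rep(0.05, 4),
                 beta = 0.7 * a, seBeta = c(0.5, 1, 2, 0.7))
  expect_equal(slope(fitWeightedMedian(d, nBoot = 50, seed = 1)), 0.7)
  ## equal weights, sorted ratios (1,2,3): percentiles (1/6,1/2,5/6)
  d2 <- MRSummary(alpha = c(1, 1, 1), seAlpha = rep(0, 3),
                  beta = c(1, 2, 3), seBeta = c(1, 1, 1))
  expect_equal(slope(fitWeightedMedian(d2, nBoot = 50, seed = 1)), 2)
  ## direct check of the interpolation rule against hand computation:
  ## weights (4, 1) at ratios (1, 2) -> percentiles (0.4, 0.9),
  ## interpolating 0.5 gives 1.2
  expect_equal(pleioMR:::weightedMedian(c(1, 2), c(4, 1)), 1.2)
  ## dominant first weight pulls the median towards its ratio:
  ## weights (10, 1) -> percentiles (5/11, 10.5/11), interpolate at 0.5
  expect_equal(pleioMR:::weightedMedian(c(1, 2), c(10, 1)),
               1 + (0.5 - 5 / 11) / (10.5 / 11 - 5 / 11))
  ## a single ratio sits exactly at the median
  expect_equal(pleioMR:::weightedMedian(2, 5), 2)
  ## errors
  dz <- MRSummary(alpha = c(0, 1), seAlpha = c(0, 0),
                  beta = c(1, 1), seBeta = c(1, 1))
  expect_error(fitWeightedMedian(dz, nBoot = 10), "ratio")
  expect_error(fitWeightedMedian(d2, nBoot = 1), "nBoot")
})

test_that("weighted median is invariant to SNP order and seeded", {
  d <- randomSummary(15, seed = 77, oriented = TRUE)
  f1 <- fitWeightedMedian(d, nBoot = 200, seed = 9)
  perm <- sample(15)
  dp <- MRSummary(alpha = alphaHat(d)[perm], seAlpha = seAlpha(d)[perm],
                  beta = betaHat(d)[perm], seBeta = seBeta(d)[perm])
  f2 <- fitWeightedMedian(dp, nBoot = 200, seed = 9)
  expect_equal(slope(f2), slope(f1))
  ## the bootstrap scale is only stochastically order-invariant
  expect_equal(slopeScale(f2), slopeScale(f1), tolerance = 0.1)
  ## fixed alpha when seAlpha is zero: bootstrap still defined
  d0 <- MRSummary(alpha = c(1, 2, 3), seAlpha = rep(0, 3),
                  beta = c(0.5, 1.2, 1.9), seBeta = rep(0.5, 3))
  expect_gt(slopeScale(fitWeightedMedian(d0, nBoot = 200, seed = 3)), 0)
})

test_that("estimators are invariant to joint sign flips of (alpha, beta)", {
  d <- randomSummary(12, seed = 91, oriented = TRUE)
  set.seed(4)
  flip <- sample(c(1, -1), 12, replace = TRUE)
  df <- MRSummary(alpha = alphaHat(d) * flip, seAlpha = seAlpha(d),
                  beta = betaHat(d) * flip, seBeta = seBeta(d))
  prior <- MRPrior(varPhi = 1e-2)
  for (pair in list(
    list(fitIVW(d), fitIVW(df)),
    list(fitMREgger(d), fitMREgger(df)),
    list(fitBayesMREgger(d, prior), fitBayesMREgger(df, prior)),
    list(fitWeightedMedian(d, nBoot = 300, seed = 2),
         fitWeightedMedian(df, nBoot = 300, seed = 2))
  )) {
    expect_equal(slope(pair[[2]]), slope(pair[[1]]))
    expect_equal(slopeScale(pair[[2]]), slopeScale(pair[[1]]))
    expect_equal(slopeInterval(pair[[2]]), slopeInterval(pair[[1]]))
    expect_equal(intercept(pair[[2]]), intercept(pair[[1]]))
  }
})

test_that("rescaling the outcome by c > 0 scales estimates by c", {
  d <- randomSummary(14, seed = 55, oriented = TRUE)
  cc <- 3.7
  dc <- MRSummary(alpha = alphaHat(d), seAlpha = seAlpha(d),
                  beta = cc * betaHat(d), seBeta = cc * seBeta(d))
  expect_equal(slope(fitIVW(dc)), cc * slope(fitIVW(d)))
  fE <- fitMREgger(d)
  fEc <- fitMREgger(dc)
  expect_equal(slope(fEc), cc * slope(fE))
  expect_equal(intercept(fEc), cc * intercept(fE))
  ## BMRE with prior means scaled by c and variances by c^2
  p <- MRPrior(muPhi = 0.02, varPhi = 1e-3, muTheta = 0.1, varTheta = 2)
  pc <- MRPrior(muPhi = cc * 0.02, varPhi = cc^2 * 1e-3,
                muTheta = cc * 0.1, varTheta = cc^2 * 2)
  expect_equal(slope(fitBayesMREgger(dc, pc)),
               cc * slope(fitBayesMREgger(d, p)))
  ## WM point estimate (ratios scale linearly)
  expect_equal(slope(fitWeightedMedian(dc, nBoot = 10, seed = 1)),
               cc * slope(fitWeightedMedian(d, nBoot = 10, seed = 1)))
})

test_that("random-effects scales never drop below the fixed-effect scale", {
  for (seed in 1:10) {
    d <- randomSummary(sample(5:20, 1), seed = seed + 200)
    f <- fitIVW(d)
    Omega <- buildWeightMatrix(orientInstruments(d))
    a <- abs(alphaHat(d))
    fixedScale <- sqrt(drop(solve(t(a) %*% solve(Omega) %*% a)))
    expect_gte(slopeScale(f), fixedScale - 1e-12)
  }
})
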