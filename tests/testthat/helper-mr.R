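## Shared fixtures and independent oracles for the estimator tests.

## Random summary-statistics instance; alpha signs mixed unless oriented.
randomSummary <- function(J, seed, oriented = FALSE, corr = NULL) {
  set.seed(seed)
  alpha <- runif(J, 0.3, 3) * sample(c(-1, 1), J, replace = TRUE)
  if (oriented) alpha <- abs(alpha)
  MRSummary(
    alpha = alpha,
    seAlpha = runif(J, 0.01, 0.2),
    beta = 0.4 * alpha + rnorm(J, sd = 0.3),
    seBeta = runif(J, 0.2, 1.5),
    corr = corr
  )
}

## Random correlation matrix: unit-diagonal, symmetric, positive definite.
randomCorr <- function(J, seed) {
  set.seed(seed)
  M <- matrix(rnorm(J * J), J)
  S <- crossprod(M) + diag(J)
  stats::cov2cor(S)
}

## Independent GLS oracle: whiten by the Cholesky factor of Omega and fit
## with lm() (QR decomposition), then apply the clamped multiplicative
## random-effects scale. Deliberately avoids the package's normal-equations
## path.
oracleGLS <- function(data, withIntercept) {
  data <- suppressWarnings(orientInstruments(data))
  Omega <- tcrossprod(seBeta(data)) * data@corr
  Lt <- chol(Omega)
  X <- if (withIntercept) cbind(1, alphaHat(data)) else cbind(alphaHat(data))
  Xw <- backsolve(Lt, X, transpose = TRUE)
  yw <- backsolve(Lt, betaHat(data), transpose = TRUE)
  fit <- lm(yw ~ 0 + Xw)
  k <- ncol(X)
  J <- nInstruments(data)
  ## weighted residuals on the original scale, per the estimator's rule
  resid <- betaHat(data) - drop(X %*% coef(fit))
  eps <- sqrt(diag(solve(Omega))) * resid
  sigma2Hat <- sum(eps^2) / (J - k)
  covUnscaled <- solve(crossprod(Xw))
  list(
    coef = unname(coef(fit)),
    scales = sqrt(max(sigma2Hat, 1) * diag(covUnscaled)),
    sigma2Hat = sigma2Hat
  )
}

## Ridge-form oracle for the conjugate posterior mean: augmented-data
## least squares. Prior rows sqrt(1/var) * e_i with target sqrt(1/var) * mu
## appended to the whitened design reproduce the posterior mean exactly.
oracleRidge <- function(data, prior) {
  data <- suppressWarnings(orientInstruments(data))
  Omega <- tcrossprod(seBeta(data)) * data@corr
  Lt <- chol(Omega)
  X <- cbind(1, alphaHat(data))
  Xw <- backsolve(Lt, X, transpose = TRUE)
  yw <- backsolve(Lt, betaHat(data), transpose = TRUE)
  Xa <- rbind(Xw, diag(c(1 / sqrt(prior@varPhi), 1 / sqrt(prior@varTheta))))
  ya <- c(yw, prior@muPhi / sqrt(prior@varPhi),
          prior@muTheta / sqrt(prior@varTheta))
  unname(coef(lm(ya ~ 0 + Xa)))
}

## Relative agreement to a number of significant digits.
expect_sigdigits <- function(actual, expected, digits = 10) {
  scale <- pmax(abs(expected), .Machine$double.eps)
  expect_lt(max(abs(actual - expected) / scale), 10^(-digits))
}
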