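#' Construct a prior specification for the Bayesian MR-Egger
#'
#' @param muPhi prior mean of the pleiotropy intercept (default 0).
#' @param varPhi prior variance of the intercept.
#' @param muTheta prior mean of the causal slope (default 0).
#' @param varTheta prior variance of the slope (default 10, weakly
#'   informative on typical MR effect scales).
#' @return an [MRPrior-class] object.
#' @examples
#' MRPrior(varPhi = elicitPriorVariance(0.05, 0.95))
#' @export
MRPrior <- function(muPhi = 0, varPhi, muTheta = 0, varTheta = 10) {
  new("MRPrior", muPhi = as.numeric(muPhi), muTheta = as.numeric(muTheta),
      varPhi = as.numeric(varPhi), varTheta = as.numeric(varTheta))
}

setMethod("show", "MRPrior", function(object) {
  cat(sprintf(
    "MRPrior: intercept ~ N(%g, %g), slope ~ N(%g, %g)\n",
    object@muPhi, object@varPhi, object@muTheta, object@varTheta
  ))
  invisible(NULL)
})

#' Hyperparameter grid of Bayesian MR-Egger priors
#'
#' Expands intercept prior means and variances into a list of
#' [MRPrior-class] objects (slope prior fixed), defaulting to the grid
#' used in the simulation study: \eqn{\mu_\varphi \in \{0, 0.05, 0.10,
#' 0.15\}}, \eqn{\sigma^2_{\mu\varphi} \in \{10, 10^{-2}, 10^{-2.4},
#' 10^{-2.7}, 10^{-3}\}}, slope prior N(0, 10).
#'
#' @param muPhi vector of intercept prior means.
#' @param varPhi vector of intercept prior variances.
#' @param muTheta,varTheta slope prior mean and variance.
#' @return a named list of [MRPrior-class] objects.
#' @export
priorGrid <- function(muPhi = c(0, 0.05, 0.10, 0.15),
                      varPhi = 10^c(1, -2, -2.4, -2.7, -3),
                      muTheta = 0, varTheta = 10) {
  grid <- expand.grid(muPhi = muPhi, varPhi = varPhi)
  priors <- lapply(seq_len(nrow(grid)), function(i) {
    MRPrior(muPhi = grid$muPhi[i], varPhi = grid$varPhi[i],
            muTheta = muTheta, varTheta = varTheta)
  })
  names(priors) <- sprintf("muPhi=%g,varPhi=%g", grid$muPhi, grid$varPhi)
  priors
}

## ---- internal fitting machinery ----------------------------------------

## Residual dispersion of a weighted fit: sigma2Hat = (1/(J-k)) * sum of
## squared precision-weighted residuals; the multiplicative random-effects
## rule uses it only when it exceeds 1 (fixed-effect scale otherwise).
residualScale <- function(design, response, weightMatrix, coefficients, k) {
  design <- as.matrix(design)
  J <- length(response)
  if (J <= k) {
    stop("insufficient instruments: need more SNPs (J = ", J,
         ") than regression parameters (k = ", k, ")")
  }
  raw <- response - drop(design %*% coefficients)
  eps <- sqrt(diag(solve(weightMatrix))) * raw
  sigma2Hat <- sum(eps^2) / (J - k)
  list(sigma2Hat = sigma2Hat, sigma2Used = max(sigma2Hat, 1))
}

## Generalized-least-squares core shared by IVW and MR-Egger: solves the
## normal equations (A' Omega^-1 A) c = A' Omega^-1 B and returns the
## coefficient vector with its clamped-dispersion covariance.
glsFit <- function(design, response, Omega, k) {
  design <- as.matrix(design)
  Wi <- solve(Omega)
  xtwx <- crossprod(design, Wi %*% design)
  if (rcond(xtwx) < .Machine$double.eps * 100) {
    stop("singular weighted design: instruments are collinear ",
         "(identical exposure effects?)")
  }
  xtwxInv <- solve(xtwx)
  coefs <- drop(xtwxInv %*% crossprod(design, Wi %*% response))
  sc <- residualScale(design, response, Omega, coefs, k)
  list(coefficients = coefs,
       scales = sqrt(sc$sigma2Used * diag(xtwxInv)),
       sigma2Hat = sc$sigma2Hat, sigma2Used = sc$sigma2Used)
}

newEstimate <- function(method, slope, slopeScale, sigma2Hat, sigma2Used,
                        ciLevel, k, intercept = NA_real_,
                        interceptScale = NA_real_) {
  z <- qnorm((1 + ciLevel) / 2)
  slopeInt <- slope + c(-1, 1) * z * slopeScale
  intInt <- if (is.na(intercept)) c(NA_real_, NA_real_) else {
    intercept + c(-1, 1) * z * interceptScale
  }
  excludesZero <- function(ci) {
    if (any(is.na(ci))) NA else ci[1] > 0 || ci[2] < 0
  }
  new("MREstimate",
    method = method, slope = slope, slopeScale = slopeScale,
    intercept = intercept, interceptScale = interceptScale,
    sigma2Hat = sigma2Hat, sigma2Used = sigma2Used, ciLevel = ciLevel,
    slopeInterval = slopeInt, interceptInterval = intInt,
    rejectSlope = excludesZero(slopeInt),
    rejectIntercept = excludesZero(intInt),
    k = as.integer(k)
  )
}

## ---- estimators ---------------------------------------------------------

#' Inverse-variance weighted (IVW) estimator
#'
#' Weighted regression of the SNP-outcome effects on the SNP-exposure
#' effects through the origin, \eqn{\hat\theta_{IVW} = (A'\Omega^{-1}
#' A)^{-1} A'\Omega^{-1}B}, with standard error
#' \eqn{\sqrt{\hat\sigma^2_\varepsilon (A'\Omega^{-1}A)^{-1}}} where the
#' residual dispersion enters only when above 1 (multiplicative
#' random-effects model). Unbiased when pleiotropy is absent or balanced
#' under InSIDE.
#'
#' @param data an [MRSummary-class] object with at least 2 instruments.
#' @param ciLevel two-sided interval level (default 0.95).
#' @return an [MREstimate-class] object (no intercept fields).
#' @examples
#' d <- MRSummary(alpha = c(1, 2), seAlpha = c(0, 0),
#'                beta = c(0.5, 1), seBeta = c(1, 1))
#' slope(fitIVW(d))  # 0.5: exact fit through the origin
#' @export
fitIVW <- function(data, ciLevel = 0.95) {
  data <- orientInstruments(data)
  J <- nInstruments(data)
  if (J < 2) stop("IVW needs at least 2 instruments, got ", J)
  Omega <- buildWeightMatrix(data)
  fit <- glsFit(cbind(data@alpha), data@beta, Omega, k = 1)
  newEstimate("IVW", slope = fit$coefficients[1],
              slopeScale = fit$scales[1], sigma2Hat = fit$sigma2Hat,
              sigma2Used = fit$sigma2Used, ciLevel = ciLevel, k = 1)
}

#' MR-Egger estimator
#'
#' Weighted regression of SNP-outcome on SNP-exposure effects with a
#' free intercept. The intercept \eqn{\hat\varphi_{MRE}} estimates the
#' average directional pleiotropy; the slope \eqn{\hat\theta_{MRE}} is
#' a pleiotropy-corrected causal estimate, consistent under the InSIDE
#' assumption (pleiotropic effects independent of instrument strengths).
#' Instruments are oriented internally so all exposure effects are
#' non-negative.
#'
#' @inheritParams fitIVW
#' @param data an [MRSummary-class] object with at least 3 instruments.
#' @return an [MREstimate-class] object with intercept fields populated.
#' @export
fitMREgger <- function(data, ciLevel = 0.95) {
  data <- orientInstruments(data)
  J <- nInstruments(data)
  if (J < 3) stop("MR-Egger needs at least 3 instruments, got ", J)
  Omega <- buildWeightMatrix(data)
  fit <- glsFit(cbind(1, data@alpha), data@beta, Omega, k = 2)
  newEstimate("MRE", slope = fit$coefficients[2],
              slopeScale = fit$scales[2], sigma2Hat = fit$sigma2Hat,
              sigma2Used = fit$sigma2Used, ciLevel = ciLevel, k = 2,
              intercept = fit$coefficients[1],
              interceptScale = fit$scales[1])
}

#' Bayesian MR-Egger (BMRE) estimator
#'
#' Conjugate Bayesian version of the Egger regression: an independent
#' normal prior on (intercept, slope) with mean \eqn{\mu_0} and
#' covariance \eqn{\Sigma_0 = diag(\sigma^2_{\mu\varphi},
#' \sigma^2_{\mu\theta})} yields the closed-form normal posterior
#' \deqn{\mu_N = (A'\Omega^{-1}A + \lambda_0)^{-1} (\lambda_0 \mu_0 +
#' A'\Omega^{-1}B), \quad \Sigma_N = \hat\sigma^2_\varepsilon
#' (A'\Omega^{-1}A + \lambda_0)^{-1},}
#' with \eqn{\lambda_0 = \Sigma_0^{-1}} and the residual dispersion
#' evaluated at the posterior mean (k = 2) and clamped at 1 as for the
#' frequentist fits. A tight zero-mean prior on the intercept recovers
#' IVW; vague priors recover MR-Egger — weakly informative intercept
#' priors interpolate, buying back power while allowing a plausible
#' degree of directional pleiotropy.
#'
#' @inheritParams fitIVW
#' @param prior an [MRPrior-class] object.
#' @return an [MREstimate-class]; scales are posterior SDs and intervals
#'   central credible intervals.
#' @examples
#' d <- MRSummary(alpha = 1:5, seAlpha = rep(0, 5),
#'                beta = 0.3 + 0.7 * (1:5) + c(0.1, -0.1, 0, 0.1, -0.1),
#'                seBeta = rep(0.5, 5))
#' fitBayesMREgger(d, MRPrior(varPhi = 1e-3))
#' @export
fitBayesMREgger <- function(data, prior, ciLevel = 0.95) {
  stopifnot(is(prior, "MRPrior"))
  validObject(prior)
  data <- orientInstruments(data)
  J <- nInstruments(data)
  if (J < 1) stop("BMRE needs at least 1 instrument")
  Omega <- buildWeightMatrix(data)
  design <- cbind(1, data@alpha)
  Wi <- solve(Omega)
  lambda0 <- diag(c(1 / prior@varPhi, 1 / prior@varTheta))
  mu0 <- c(prior@muPhi, prior@muTheta)
  prec <- crossprod(design, Wi %*% design) + lambda0
  if (rcond(prec) < .Machine$double.eps * 100) {
    stop("singular posterior precision matrix")
  }
  precInv <- solve(prec)
  muN <- drop(precInv %*% (lambda0 %*% mu0 +
                             crossprod(design, Wi %*% data@beta)))
  ## dispersion from residuals at the posterior mean, as in the
  ## frequentist fits, with the same clamp-at-1 rule
  sc <- if (J > 2) {
    residualScale(design, data@beta, Omega, muN, k = 2)
  } else {
    list(sigma2Hat = NA_real_, sigma2Used = 1)
  }
  SigmaN <- sc$sigma2Used * precInv
  newEstimate("BMRE", slope = muN[2], slopeScale = sqrt(SigmaN[2, 2]),
              sigma2Hat = sc$sigma2Hat, sigma2Used = sc$sigma2Used,
              ciLevel = ciLevel, k = 2,
              intercept = muN[1], interceptScale = sqrt(SigmaN[1, 1]))
}

## Weighted median of ratio estimates: sorted ratios r_(j) carry weights
## w_(j); the j-th sorted ratio sits at percentile (s_j - w_j/2)/S with
## s_j the cumulative weight. Linear interpolation at 0.5; clamped to
## the extreme ratios outside the percentile range.
weightedMedian <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  approx(p, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted median (WM) estimator
#'
#' The 50th percentile of the per-SNP ratio estimates
#' \eqn{\hat\beta_j/\hat\alpha_j} under inverse-variance weights
#' \eqn{w_j = \hat\alpha_j^2/\hat\sigma^2_{\beta j}}, consistent as long
#' as at least half the total weight comes from valid (non-pleiotropic)
#' instruments. The sampling scale is estimated by a parametric
#' bootstrap: \code{nBoot} resamples of \eqn{\hat\alpha_j \sim
#' N(\hat\alpha_j, \hat\sigma^2_{\alpha j})} and \eqn{\hat\beta_j \sim
#' N(\hat\beta_j, \hat\sigma^2_{\beta j})}, re-estimating the weighted
#' median on each (a SNP with \code{seAlpha = 0} keeps its exposure
#' effect fixed).
#'
#' @inheritParams fitIVW
#' @param nBoot number of parametric bootstrap resamples (default 1000).
#' @param seed optional integer seed for the bootstrap; \code{NULL}
#'   continues the current RNG stream.
#' @return an [MREstimate-class] object (no intercept fields;
#'   \code{sigma2Hat}/\code{sigma2Used} are \code{NA}/1 as no regression
#'   dispersion is involved).
#' @export
fitWeightedMedian <- function(data, nBoot = 1000, seed = NULL,
                              ciLevel = 0.95) {
  data <- suppressWarnings(orientInstruments(data))
  J <- nInstruments(data)
  if (J < 2) stop("weighted median needs at least 2 instruments, got ", J)
  if (any(data@alpha == 0)) {
    stop("alpha is exactly 0 for some SNP: ratio estimate undefined")
  }
  if (nBoot < 2) stop("nBoot must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  w <- data@alpha^2 / data@seBeta^2
  est <- weightedMedian(data@beta / data@alpha, w)
  ## parametric bootstrap, vectorized across resamples
  aStar <- matrix(rnorm(nBoot * J, mean = rep(data@alpha, each = nBoot),
                        sd = rep(data@seAlpha, each = nBoot)),
                  nrow = nBoot)
  bStar <- matrix(rnorm(nBoot * J, mean = rep(data@beta, each = nBoot),
                        sd = rep(data@seBeta, each = nBoot)),
                  nrow = nBoot)
  seB2 <- data@seBeta^2
  boot <- vapply(seq_len(nBoot), function(i) {
    a <- aStar[i, ]
    weightedMedian(bStar[i, ] / a, a^2 / seB2)
  }, numeric(1))
  newEstimate("WM", slope = est, slopeScale = sd(boot),
              sigma2Hat = NA_real_, sigma2Used = 1,
              ciLevel = ciLevel, k = 1)
}

## ---- MREstimate accessors & display -------------------------------------

#' Accessors for MREstimate objects
#'
#' @param object an [MREstimate-class] object.
#' @return the corresponding component: point estimate, scale,
#'   two-element interval, or rejection flag.
#' @name MREstimate-accessors
NULL

#' @rdname MREstimate-accessors
#' @export
setMethod("slope", "MREstimate", function(object) object@slope)

#' @rdname MREstimate-accessors
#' @export
setMethod("slopeScale", "MREstimate", function(object) object@slopeScale)

#' @rdname MREstimate-accessors
#' @export
setMethod("intercept", "MREstimate", function(object) object@intercept)

#' @rdname MREstimate-accessors
#' @export
setMethod("interceptScale", "MREstimate",
          function(object) object@interceptScale)

#' @rdname MREstimate-accessors
#' @export
setMethod("slopeInterval", "MREstimate", function(object) {
  object@slopeInterval
})

#' @rdname MREstimate-accessors
#' @export
setMethod("interceptInterval", "MREstimate", function(object) {
  object@interceptInterval
})

#' @rdname MREstimate-accessors
#' @export
setMethod("rejectSlope", "MREstimate", function(object) object@rejectSlope)

#' @rdname MREstimate-accessors
#' @export
setMethod("rejectIntercept", "MREstimate", function(object) {
  object@rejectIntercept
})

setMethod("show", "MREstimate", function(object) {
  lvl <- 100 * object@ciLevel
  cat(sprintf("%s estimate (%g%% interval)\n", object@method, lvl))
  cat(sprintf("  slope:     %8.4f (%.4f; %.4f)  scale %.4f\n",
              object@slope, object@slopeInterval[1],
              object@slopeInterval[2], object@slopeScale))
  if (!is.na(object@intercept)) {
    cat(sprintf("  intercept: %8.4f (%.4f; %.4f)  scale %.4f\n",
                object@intercept, object@interceptInterval[1],
                object@interceptInterval[2], object@interceptScale))
  }
  if (!is.na(object@sigma2Hat)) {
    cat(sprintf("  residual dispersion %.4f (used: %.4f)\n",
                object@sigma2Hat, object@sigma2Used))
  }
  invisible(NULL)
})

#' @describeIn MREstimate-accessors one-row data.frame of all fields,
#'   suitable for binding across methods.
#' @param x an [MREstimate-class] object.
#' @param row.names,optional,... passed on conventionally; unused.
#' @param exponentiate report point estimates and interval bounds on the
#'   odds-ratio scale (for log-odds outcome effects).
#' @export
as.data.frame.MREstimate <- function(x, row.names = NULL, optional = FALSE,
                                     exponentiate = FALSE, ...) {
  tf <- if (exponentiate) exp else identity
  data.frame(
    method = x@method,
    slope = tf(x@slope), slope_scale = x@slopeScale,
    slope_lo = tf(x@slopeInterval[1]), slope_hi = tf(x@slopeInterval[2]),
    intercept = tf(x@intercept), intercept_scale = x@interceptScale,
    intercept_lo = tf(x@interceptInterval[1]),
    intercept_hi = tf(x@interceptInterval[2]),
    sigma2_hat = x@sigma2Hat, sigma2_used = x@sigma2Used,
    reject_slope = x@rejectSlope, reject_intercept = x@rejectIntercept,
    ci_level = x@ciLevel, k = x@k,
    stringsAsFactors = FALSE
  )
}

setMethod("as.data.frame", "MREstimate", as.data.frame.MREstimate)
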