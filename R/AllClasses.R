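#' @import methods
#' @importFrom stats qnorm rnorm rbinom runif lm coef vcov approx sd var
#'   pnorm quantile
NULL

#' Two-sample Mendelian randomization summary statistics
#'
#' Container for per-instrument (per-SNP) summary statistics of a
#' two-sample Mendelian randomization study: the marginal SNP-exposure
#' associations \eqn{\hat\alpha_j} with standard errors
#' \eqn{\hat\sigma_{\alpha j}}, the marginal SNP-outcome associations
#' \eqn{\hat\beta_j} with standard errors \eqn{\hat\sigma_{\beta j}},
#' and an optional between-SNP correlation matrix \eqn{\rho_{jk}}
#' (identity for independent instruments).
#'
#' @slot snp character vector of instrument identifiers.
#' @slot alpha numeric, SNP-exposure effects (exposure units per allele).
#' @slot seAlpha numeric, standard errors of \code{alpha}; may be zero
#'   when the exposure association is treated as known.
#' @slot beta numeric, SNP-outcome effects (outcome or log-odds units).
#' @slot seBeta numeric, standard errors of \code{beta}; strictly positive.
#' @slot corr J x J between-SNP correlation matrix (unit diagonal,
#'   symmetric, positive definite); identity when SNPs are independent.
#'
#' @seealso [MRSummary()] for construction, [readMRSummary()] for file
#'   input, [orientInstruments()], and the estimators [fitIVW()],
#'   [fitMREgger()], [fitBayesMREgger()], [fitWeightedMedian()].
#' @export
setClass("MRSummary",
  representation(
    snp = "character",
    alpha = "numeric",
    seAlpha = "numeric",
    beta = "numeric",
    seBeta = "numeric",
    corr = "matrix"
  )
)

setValidity("MRSummary", function(object) {
  msg <- character()
  J <- length(object@snp)
  lens <- c(
    alpha = length(object@alpha), seAlpha = length(object@seAlpha),
    beta = length(object@beta), seBeta = length(object@seBeta)
  )
  if (any(lens != J)) {
    msg <- c(msg, sprintf(
      "field lengths differ: snp has %d entries but %s",
      J, paste(sprintf("%s has %d", names(lens)[lens != J], lens[lens != J]),
               collapse = ", ")
    ))
  }
  num <- c(object@alpha, object@seAlpha, object@beta, object@seBeta)
  if (length(num) && any(!is.finite(num))) {
    msg <- c(msg, "summary statistics must be finite")
  }
  if (any(object@seBeta <= 0)) {
    msg <- c(msg, "all seBeta must be > 0")
  }
  if (any(object@seAlpha < 0)) {
    msg <- c(msg, "all seAlpha must be >= 0")
  }
  if (!all(dim(object@corr) == c(J, J))) {
    msg <- c(msg, sprintf("corr must be %d x %d", J, J))
  } else if (J > 0) {
    if (max(abs(object@corr - t(object@corr))) > 1e-8) {
      msg <- c(msg, "corr must be symmetric")
    }
    if (max(abs(diag(object@corr) - 1)) > 1e-8) {
      msg <- c(msg, "corr must have unit diagonal")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Prior specification for the Bayesian MR-Egger estimator
#'
#' Hyperparameters of the independent bivariate normal prior on the
#' MR-Egger intercept (average directional pleiotropy, \eqn{\varphi})
#' and slope (causal effect, \eqn{\theta}): prior means
#' \eqn{\mu_\varphi, \mu_\theta} and prior variances
#' \eqn{\sigma^2_{\mu\varphi}, \sigma^2_{\mu\theta}}.
#'
#' Setting \code{varPhi} small with \code{muPhi = 0} pulls the fit
#' towards the IVW estimator (no pleiotropy); letting both variances
#' grow recovers the frequentist MR-Egger fit.
#'
#' @slot muPhi prior mean of the intercept (outcome units).
#' @slot muTheta prior mean of the slope.
#' @slot varPhi prior variance of the intercept, > 0.
#' @slot varTheta prior variance of the slope, > 0.
#'
#' @seealso [MRPrior()], [fitBayesMREgger()], [elicitPriorVariance()].
#' @export
setClass("MRPrior",
  representation(
    muPhi = "numeric",
    muTheta = "numeric",
    varPhi = "numeric",
    varTheta = "numeric"
  )
)

setValidity("MRPrior", function(object) {
  msg <- character()
  for (s in c("muPhi", "muTheta", "varPhi", "varTheta")) {
    v <- slot(object, s)
    if (length(v) != 1 || !is.finite(v)) {
      msg <- c(msg, sprintf("%s must be a single finite number", s))
    }
  }
  if (length(object@varPhi) == 1 && is.finite(object@varPhi) &&
      object@varPhi <= 0) {
    msg <- c(msg, "varPhi must be > 0")
  }
  if (length(object@varTheta) == 1 && is.finite(object@varTheta) &&
      object@varTheta <= 0) {
    msg <- c(msg, "varTheta must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Result of a summary-statistics MR fit
#'
#' Point estimates, scales (standard errors or posterior standard
#' deviations), symmetric intervals and interval-excludes-zero flags for
#' one estimator. Intercept fields are \code{NA} for estimators without
#' a pleiotropy intercept (IVW, weighted median).
#'
#' @slot method one of \code{"IVW"}, \code{"MRE"}, \code{"BMRE"},
#'   \code{"WM"}.
#' @slot slope causal-effect estimate (posterior mean for BMRE).
#' @slot slopeScale standard error / posterior SD / bootstrap SD of the
#'   slope.
#' @slot intercept average-pleiotropy estimate (MRE/BMRE only).
#' @slot interceptScale scale of the intercept.
#' @slot sigma2Hat residual dispersion \eqn{\hat\sigma^2_\varepsilon}
#'   before clamping.
#' @slot sigma2Used \code{max(sigma2Hat, 1)}: the multiplicative
#'   random-effects rule inflates scales only under overdispersion.
#' @slot ciLevel interval level (default 0.95).
#' @slot slopeInterval,interceptInterval symmetric (credible) intervals.
#' @slot rejectSlope,rejectIntercept does the interval exclude zero?
#' @slot k number of regression parameters (1 for IVW, 2 for MRE/BMRE).
#'
#' @export
setClass("MREstimate",
  representation(
    method = "character",
    slope = "numeric",
    slopeScale = "numeric",
    intercept = "numeric",
    interceptScale = "numeric",
    sigma2Hat = "numeric",
    sigma2Used = "numeric",
    ciLevel = "numeric",
    slopeInterval = "numeric",
    interceptInterval = "numeric",
    rejectSlope = "logical",
    rejectIntercept = "logical",
    k = "integer"
  )
)

setValidity("MREstimate", function(object) {
  msg <- character()
  if (!object@method %in% c("IVW", "MRE", "BMRE", "WM")) {
    msg <- c(msg, "method must be one of IVW, MRE, BMRE, WM")
  }
  if (is.finite(object@slopeScale) && object@slopeScale <= 0) {
    msg <- c(msg, "slopeScale must be > 0")
  }
  if (is.finite(object@sigma2Used) && object@sigma2Used < 1) {
    msg <- c(msg, "sigma2Used must be >= 1")
  }
  if (length(object@slopeInterval) == 2 &&
      all(is.finite(object@slopeInterval)) &&
      diff(object@slopeInterval) < 0) {
    msg <- c(msg, "slopeInterval bounds must be ordered")
  }
  if (length(msg)) msg else TRUE
})

#' Simulation scenario configuration
#'
#' All parameters of one two-sample Mendelian randomization simulation
#' scenario: cohort size, number of instruments, minor allele frequency,
#' the causal effect, the per-SNP parameter ranges (instrument strength
#' \eqn{\alpha_j}, pleiotropy \eqn{\varphi_j}, confounder loading
#' \eqn{\omega_{1j}} governing InSIDE violation), the proportion of
#' pleiotropic SNPs, confounder effects on exposure and outcome, and the
#' noise dispersion.
#'
#' @slot scenario label ("I".."V" for the built-in presets, or "custom").
#' @slot n subjects per cohort.
#' @slot J number of SNPs.
#' @slot maf minor allele frequency, in (0, 0.5).
#' @slot theta causal effect of exposure on outcome.
#' @slot alphaRange range of Unif draw for instrument strengths.
#' @slot phiRange range of Unif draw for pleiotropic effects.
#' @slot q probability each SNP is pleiotropic.
#' @slot omega1Range range of Unif draw for SNP-confounder effects
#'   ((0,0) when InSIDE holds).
#' @slot omega2 confounder effect on the exposure.
#' @slot omega3 confounder effect on the outcome.
#' @slot noise dispersion of the three error terms; interpreted per
#'   \code{noiseParam}.
#' @slot noiseParam \code{"variance"} (default) or \code{"sd"}.
#' @slot seed RNG seed (NA to use the current RNG state).
#'
#' @seealso [scenarioPreset()], [simulateCohort()], [makeTwoSample()].
#' @export
setClass("MRScenario",
  representation(
    scenario = "character",
    n = "integer",
    J = "integer",
    maf = "numeric",
    theta = "numeric",
    alphaRange = "numeric",
    phiRange = "numeric",
    q = "numeric",
    omega1Range = "numeric",
    omega2 = "numeric",
    omega3 = "numeric",
    noise = "numeric",
    noiseParam = "character",
    seed = "numeric"
  )
)

setValidity("MRScenario", function(object) {
  msg <- character()
  if (object@n < 1 || object@J < 1) msg <- c(msg, "n and J must be positive")
  if (!(object@maf > 0 && object@maf < 0.5)) {
    msg <- c(msg, "maf must lie in (0, 0.5)")
  }
  if (object@q < 0 || object@q > 1) msg <- c(msg, "q must lie in [0, 1]")
  for (s in c("alphaRange", "phiRange", "omega1Range")) {
    r <- slot(object, s)
    if (length(r) != 2 || r[1] > r[2]) {
      msg <- c(msg, sprintf("%s must be an ordered pair (low <= high)", s))
    }
  }
  if (object@noise < 0) msg <- c(msg, "noise must be >= 0")
  if (!object@noiseParam %in% c("variance", "sd")) {
    msg <- c(msg, "noiseParam must be 'variance' or 'sd'")
  }
  if (length(msg)) msg else TRUE
})
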