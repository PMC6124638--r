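#' Build a simulation scenario configuration
#'
#' Low-level constructor; most users want [scenarioPreset()] for the
#' five study scenarios.
#'
#' @param n subjects per cohort (default 1000).
#' @param J number of SNPs (default 20).
#' @param maf minor allele frequency (default 0.30).
#' @param theta causal effect of exposure on outcome (0 or 0.05 in the
#'   study scenarios).
#' @param alphaRange Unif range for instrument strengths (default
#'   (0.5, 4)).
#' @param phiRange Unif range for pleiotropic effects; (0, 0) for none.
#' @param q probability each SNP is pleiotropic (default 1).
#' @param omega1Range Unif range for SNP-confounder effects; (0, 0)
#'   when InSIDE holds.
#' @param omega2,omega3 confounder effects on exposure and outcome
#'   (default 1 each).
#' @param noise error dispersion of the confounder, exposure and outcome
#'   equations (default 2).
#' @param noiseParam how \code{noise} is read: \code{"sd"} (default,
#'   i.e. errors N(0, 2^2)) or \code{"variance"}. The default is the
#'   reading under which the simulator reproduces the study's reported
#'   operating characteristics; see the methods vignette.
#' @param scenario label recorded in the object.
#' @param seed RNG seed applied by the simulation entry points
#'   (\code{NA} to use the current RNG state).
#' @return an [MRScenario-class] object.
#' @export
MRScenario <- function(n = 1000, J = 20, maf = 0.30, theta = 0,
                       alphaRange = c(0.5, 4), phiRange = c(0, 0), q = 1,
                       omega1Range = c(0, 0), omega2 = 1, omega3 = 1,
                       noise = 2, noiseParam = "sd",
                       scenario = "custom", seed = NA_real_) {
  new("MRScenario",
    scenario = scenario, n = as.integer(n), J = as.integer(J),
    maf = maf, theta = theta, alphaRange = as.numeric(alphaRange),
    phiRange = as.numeric(phiRange), q = q,
    omega1Range = as.numeric(omega1Range),
    omega2 = omega2, omega3 = omega3,
    noise = noise, noiseParam = noiseParam, seed = as.numeric(seed)
  )
}

setMethod("show", "MRScenario", function(object) {
  cat(sprintf("MRScenario '%s': n = %d per cohort, J = %d SNPs, maf = %g\n",
              object@scenario, object@n, object@J, object@maf))
  cat(sprintf("  theta = %g; alpha ~ U(%g, %g)\n",
              object@theta, object@alphaRange[1], object@alphaRange[2]))
  cat(sprintf("  pleiotropy: phi ~ U(%g, %g) with probability q = %g\n",
              object@phiRange[1], object@phiRange[2], object@q))
  cat(sprintf("  confounding: omega1 ~ U(%g, %g), omega2 = %g, omega3 = %g\n",
              object@omega1Range[1], object@omega1Range[2],
              object@omega2, object@omega3))
  cat(sprintf("  noise %s = %g; seed = %s\n", object@noiseParam,
              object@noise,
              if (is.na(object@seed)) "current RNG" else
                format(object@seed)))
  invisible(NULL)
})

#' Scenario presets of the simulation study
#'
#' The five study scenarios, all with n = 1000 per cohort, J = 20 SNPs,
#' MAF 0.30, instrument strengths \eqn{\alpha_j \sim U(0.5, 4)} and
#' confounder effects \eqn{\omega_2 = \omega_3 = 1}:
#' \describe{
#'   \item{I}{no pleiotropy (\eqn{\varphi_j = 0}), InSIDE holds
#'     (\eqn{\omega_{1j} = 0}).}
#'   \item{II}{all SNPs pleiotropic, \eqn{\varphi_j \sim U(0, 0.2)},
#'     InSIDE holds.}
#'   \item{III}{\eqn{\varphi_j \sim U(0, 0.2)} and InSIDE violated via
#'     \eqn{\omega_{1j} \sim U(0, 0.5)}.}
#'   \item{IV}{partial pleiotropy: each SNP pleiotropic with probability
#'     \code{q} in \{0.1, 0.2, 0.3, 0.4\}, \eqn{\varphi_j \sim
#'     U(0, 0.5)} when pleiotropic, InSIDE holds. The mean pleiotropy is
#'     \eqn{E(\varphi_j) q = 0.25 q}.}
#'   \item{V}{partial pleiotropy (q = 0.4 by default) with InSIDE also
#'     violated: \eqn{\omega_{1j} \sim U(L, U)} for the pleiotropic
#'     SNPs, with U = B in \{0.1, 0.3, 0.6, 1.0\} and L either 0 or -B.}
#' }
#'
#' @param id scenario identifier, one of \code{"I".."V"}.
#' @param theta causal effect (default 0; the study also uses 0.05).
#' @param q proportion of pleiotropic SNPs (scenarios IV and V;
#'   default 0.4 for V).
#' @param L,U bounds of the SNP-confounder effect range (scenario V).
#' @param ... further arguments passed to [MRScenario()] (e.g.
#'   \code{seed}, \code{n}, or a \code{phiRange} override).
#' @return an [MRScenario-class] object.
#' @examples
#' scenarioPreset("II", theta = 0)
#' scenarioPreset("V", L = -1, U = 1)
#' @export
scenarioPreset <- function(id, theta = 0, q = NULL, L = NULL, U = NULL,
                           ...) {
  id <- as.character(id)
  base <- list(theta = theta, scenario = id, ...)
  args <- switch(id,
    "I" = list(phiRange = c(0, 0), q = 1, omega1Range = c(0, 0)),
    "II" = list(phiRange = c(0, 0.2), q = 1, omega1Range = c(0, 0)),
    "III" = list(phiRange = c(0, 0.2), q = 1, omega1Range = c(0, 0.5)),
    "IV" = list(phiRange = c(0, 0.5),
                q = if (is.null(q)) 0.4 else q,
                omega1Range = c(0, 0)),
    "V" = list(phiRange = c(0, 0.5),
               q = if (is.null(q)) 0.4 else q,
               omega1Range = c(if (is.null(L)) 0 else L,
                               if (is.null(U)) 0.5 else U)),
    stop("unknown scenario id '", id, "' (use I, II, III, IV or V)")
  )
  do.call(MRScenario, utils::modifyList(args, base))
}

noiseSD <- function(config) {
  if (config@noiseParam == "variance") sqrt(config@noise) else config@noise
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Independent per-SNP allele-count draws with category probabilities
#' \eqn{((1-p)^2,\ 2p(1-p),\ p^2)} for counts (0, 1, 2) — i.e. each
#' genotype is Binomial(2, maf).
#'
#' @param n number of subjects.
#' @param J number of SNPs.
#' @param maf minor allele frequency, in (0, 1).
#' @return an n x J integer matrix with entries in \{0, 1, 2\}.
#' @export
simulateGenotypes <- function(n, J, maf) {
  if (!(maf > 0 && maf < 1)) stop("maf must lie in (0, 1)")
  matrix(rbinom(n * J, size = 2, prob = maf), nrow = n, ncol = J)
}

## Draw the per-SNP structural parameters shared by the two cohorts of a
## replicate: instrument strengths, pleiotropic effects (each SNP
## pleiotropic with probability q; phi and omega1 share the indicator so
## InSIDE violation attaches to the pleiotropic SNPs), confounder loadings.
drawScenarioParams <- function(config) {
  J <- config@J
  alpha <- runif(J, config@alphaRange[1], config@alphaRange[2])
  pleio <- runif(J) < config@q
  phi <- ifelse(pleio, runif(J, config@phiRange[1], config@phiRange[2]), 0)
  omega1 <- ifelse(pleio,
                   runif(J, config@omega1Range[1], config@omega1Range[2]), 0)
  list(alpha = alpha, phi = phi, omega1 = omega1)
}

#' Simulate one individual-level cohort
#'
#' Generates genotypes and then the confounder, exposure and outcome per
#' the structural equations
#' \deqn{U_i = \sum_j \omega_{1j} G_{ij} + \varepsilon_u, \quad
#'       X_i = \sum_j \alpha_j G_{ij} + \omega_2 U_i + \varepsilon_x,
#'       \quad
#'       Y_i = \sum_j \varphi_j G_{ij} + \theta X_i + \omega_3 U_i +
#'             \varepsilon_y,}
#' with independent N(0, 2) errors (2 read as the standard deviation by
#' default; see \code{noiseParam} in [MRScenario()]).
#'
#' @param config an [MRScenario-class] object. If \code{config@seed} is
#'   set the RNG is seeded first.
#' @param params optional list with per-SNP \code{alpha}, \code{phi},
#'   \code{omega1} (drawn from the scenario when omitted); used to share
#'   parameters across the two cohorts of a two-sample replicate.
#' @return a list with \code{genotypes} (n x J), \code{confounder},
#'   \code{exposure}, \code{outcome} (length-n vectors) and
#'   \code{trueAlpha}, \code{truePhi}, \code{trueOmega1}.
#' @export
simulateCohort <- function(config, params = NULL) {
  validObject(config)
  if (!is.na(config@seed)) set.seed(config@seed)
  if (is.null(params)) params <- drawScenarioParams(config)
  n <- config@n
  G <- simulateGenotypes(n, config@J, config@maf)
  s <- noiseSD(config)
  U <- drop(G %*% params$omega1) + rnorm(n, sd = s)
  X <- drop(G %*% params$alpha) + config@omega2 * U + rnorm(n, sd = s)
  Y <- drop(G %*% params$phi) + config@theta * X + config@omega3 * U +
    rnorm(n, sd = s)
  list(genotypes = G, confounder = U, exposure = X, outcome = Y,
       trueAlpha = params$alpha, truePhi = params$phi,
       trueOmega1 = params$omega1)
}

## Marginal simple regressions of a phenotype on each genotype column
## (with intercept): closed-form slope and its standard error, vectorized
## across SNPs.
marginalRegressions <- function(G, y) {
  n <- nrow(G)
  gBar <- colMeans(G)
  yBar <- mean(y)
  Gc <- sweep(G, 2, gBar)
  sxx <- colSums(Gc^2)
  if (any(sxx == 0)) return(NULL)  # caller handles constant columns
  slopes <- drop(crossprod(Gc, y)) / sxx
  ## residual SS via sum((y - yBar)^2) - slope^2 * sxx
  syy <- sum((y - yBar)^2)
  rss <- syy - slopes^2 * sxx
  se <- sqrt(pmax(rss, 0) / ((n - 2) * sxx))
  list(slope = slopes, se = se)
}

#' Generate a two-sample summary-statistics replicate
#'
#' Draws the per-SNP structural parameters once, simulates two
#' independent cohorts sharing them, and reduces them to summary
#' statistics by per-SNP simple linear regressions: exposure on genotype
#' in cohort 1 (\eqn{\hat\alpha_j, \hat\sigma_{\alpha j}}) and outcome
#' on genotype in cohort 2 (\eqn{\hat\beta_j, \hat\sigma_{\beta j}}).
#' A genotype column with no variation is re-drawn once; a second
#' failure is an error.
#'
#' @inheritParams simulateCohort
#' @param returnTruth also attach the drawn per-SNP parameters as
#'   attribute \code{"truth"}.
#' @return an [MRSummary-class] object (identity correlation).
#' @export
makeTwoSample <- function(config, returnTruth = FALSE) {
  validObject(config)
  if (!is.na(config@seed)) set.seed(config@seed)
  params <- drawScenarioParams(config)
  cfg <- config
  cfg@seed <- NA_real_  # cohorts continue the stream seeded above
  regressOnce <- function(which) {
    for (attempt in 1:2) {
      cohort <- simulateCohort(cfg, params = params)
      y <- if (which == "exposure") cohort$exposure else cohort$outcome
      fit <- marginalRegressions(cohort$genotypes, y)
      if (!is.null(fit)) return(fit)
    }
    stop("constant genotype column after re-draw: ",
         "increase n or maf")
  }
  fit1 <- regressOnce("exposure")
  fit2 <- regressOnce("outcome")
  out <- MRSummary(alpha = fit1$slope, seAlpha = fit1$se,
                   beta = fit2$slope, seBeta = fit2$se)
  if (returnTruth) attr(out, "truth") <- params
  out
}

#' Read or write a scenario configuration as YAML
#'
#' @param config an [MRScenario-class] object.
#' @param file path to a YAML file.
#' @return \code{writeScenario}: the path, invisibly;
#'   \code{readScenario}: an [MRScenario-class] object.
#' @export
writeScenario <- function(config, file) {
  slots <- slotNames("MRScenario")
  lst <- lapply(slots, function(s) slot(config, s))
  names(lst) <- slots
  yaml::write_yaml(lst, file)
  invisible(file)
}

#' @rdname writeScenario
#' @export
readScenario <- function(file) {
  lst <- yaml::read_yaml(file)
  do.call(MRScenario, lst)
}
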