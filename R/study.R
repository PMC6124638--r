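#' Run a Monte-Carlo simulation study
#'
#' For each replicate, one two-sample summary-statistics dataset is
#' generated from \code{scenario} and every requested estimator (and,
#' for BMRE, every prior) is fitted on that same dataset — sharing the
#' data across estimators removes between-method Monte-Carlo noise from
#' comparisons without affecting marginal rates. A master seed spawns
#' one child seed per replicate, logged in the output, so any replicate
#' can be reproduced in isolation.
#'
#' @param scenario an [MRScenario-class] object (its own \code{seed}
#'   slot is ignored; seeding is governed by \code{masterSeed}).
#' @param estimators character vector among \code{"IVW"}, \code{"MRE"},
#'   \code{"BMRE"}, \code{"WM"}.
#' @param priors list of [MRPrior-class] objects (required when
#'   \code{"BMRE"} is requested); each is fitted per replicate.
#' @param nReps number of replicates (the study default is 5000; smaller
#'   runs widen Monte-Carlo error proportionally).
#' @param masterSeed integer master seed.
#' @param nBoot bootstrap resamples for the weighted median.
#' @param ciLevel interval level.
#' @param verbose print progress every 500 replicates.
#' @return a data.frame with one row per replicate x estimator x prior:
#'   \code{replicate}, \code{seed}, \code{method}, \code{prior} (label,
#'   \code{NA} unless BMRE), \code{slope}, \code{slope_scale},
#'   \code{intercept}, \code{intercept_scale}, \code{reject_slope},
#'   \code{reject_intercept}. Failed fits are dropped, with the count
#'   in attribute \code{"failures"}.
#' @seealso [computeMetrics()] to reduce the table to performance
#'   metrics, [mcBounds()] for Monte-Carlo bounds on rejection rates.
#' @export
runStudy <- function(scenario, estimators = c("IVW", "MRE"),
                     priors = list(), nReps = 5000, masterSeed = 1,
                     nBoot = 1000, ciLevel = 0.95, verbose = FALSE) {
  stopifnot(nReps >= 1)
  estimators <- match.arg(estimators, c("IVW", "MRE", "BMRE", "WM"),
                          several.ok = TRUE)
  if ("BMRE" %in% estimators && !length(priors)) {
    stop("BMRE requested but no priors supplied")
  }
  priorLabels <- if (is.null(names(priors)) && length(priors)) {
    vapply(priors, function(p) {
      sprintf("muPhi=%g,varPhi=%g", p@muPhi, p@varPhi)
    }, character(1))
  } else names(priors)
  set.seed(masterSeed)
  repSeeds <- sample.int(.Machine$integer.max - 1, nReps)
  scenario@seed <- NA_real_
  rows <- vector("list", nReps)
  failures <- 0L
  oneRow <- function(fit, rep, seed, prior = NA_character_) {
    data.frame(replicate = rep, seed = seed, method = fit@method,
               prior = prior, slope = fit@slope,
               slope_scale = fit@slopeScale, intercept = fit@intercept,
               intercept_scale = fit@interceptScale,
               reject_slope = fit@rejectSlope,
               reject_intercept = fit@rejectIntercept,
               stringsAsFactors = FALSE)
  }
  for (r in seq_len(nReps)) {
    set.seed(repSeeds[r])
    dat <- makeTwoSample(scenario)
    fits <- list()
    for (est in estimators) {
      res <- tryCatch(switch(est,
        IVW = list(oneRow(fitIVW(dat, ciLevel), r, repSeeds[r])),
        MRE = list(oneRow(fitMREgger(dat, ciLevel), r, repSeeds[r])),
        WM = list(oneRow(
          fitWeightedMedian(dat, nBoot = nBoot, ciLevel = ciLevel),
          r, repSeeds[r])),
        BMRE = lapply(seq_along(priors), function(i) {
          oneRow(fitBayesMREgger(dat, priors[[i]], ciLevel),
                 r, repSeeds[r], prior = priorLabels[i])
        })
      ), error = function(e) {
        failures <<- failures + 1L
        NULL
      })
      fits <- c(fits, res)
    }
    rows[[r]] <- do.call(rbind, fits)
    if (verbose && r %% 500 == 0) {
      message("replicate ", r, "/", nReps)
    }
  }
  out <- do.call(rbind, rows)
  for (est in estimators) {
    if (est == "BMRE") next
    if (!any(out$method == est)) {
      stop("all replicates failed for estimator ", est)
    }
  }
  attr(out, "failures") <- failures
  attr(out, "masterSeed") <- masterSeed
  out
}

#' Performance metrics of a simulation study
#'
#' Reduces a replicate table to per-(estimator, prior) performance
#' metrics: bias \eqn{\bar\theta - \theta}, empirical standard error
#' (SD of the estimates, denominator n - 1), root mean square error
#' \eqn{\sqrt{bias^2 + ESE^2}}, and the slope / intercept rejection
#' rates (type-1 error when \eqn{\theta = 0}, power otherwise).
#'
#' @param table a replicate table from [runStudy()].
#' @param thetaTrue the true causal effect of the generating scenario.
#' @return a data.frame with one row per estimator x prior:
#'   \code{method}, \code{prior}, \code{n_reps}, \code{bias},
#'   \code{ese}, \code{rmse}, \code{rejection_rate},
#'   \code{intercept_rejection_rate}.
#' @export
computeMetrics <- function(table, thetaTrue) {
  if (!nrow(table)) stop("empty replicate table")
  key <- paste(table$method, ifelse(is.na(table$prior), "", table$prior))
  groups <- split(table, key)
  rows <- lapply(groups, function(g) {
    if (nrow(g) < 2) {
      stop("empirical SE undefined with a single replicate for ",
           g$method[1])
    }
    bias <- mean(g$slope) - thetaTrue
    ese <- sd(g$slope)
    data.frame(
      method = g$method[1], prior = g$prior[1], n_reps = nrow(g),
      bias = bias, ese = ese, rmse = sqrt(bias^2 + ese^2),
      rejection_rate = mean(g$reject_slope),
      intercept_rejection_rate =
        if (all(is.na(g$reject_intercept))) NA_real_
        else mean(g$reject_intercept, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$method, out$prior, na.last = FALSE), , drop = FALSE]
}

#' Monte-Carlo bounds on an empirical rejection rate
#'
#' Binomial-sampling bounds \eqn{\alpha \pm z_{0.975}
#' \sqrt{\alpha(1-\alpha)/n}} within which an empirical rejection rate
#' is consistent with its nominal value; e.g. 5000 replicates at the
#' nominal 0.05 give (0.044, 0.056).
#'
#' @param nominalAlpha nominal rejection rate, in (0, 1).
#' @param nReps number of Monte-Carlo replicates.
#' @param digits rounding for display (default 3; use \code{Inf} for
#'   unrounded bounds).
#' @return numeric vector \code{c(lower, upper)}.
#' @examples
#' mcBounds(0.05, 5000)  # 0.044 0.056
#' @export
mcBounds <- function(nominalAlpha, nReps, digits = 3) {
  stopifnot(nReps >= 1, nominalAlpha > 0, nominalAlpha < 1)
  half <- qnorm(0.975) * sqrt(nominalAlpha * (1 - nominalAlpha) / nReps)
  b <- nominalAlpha + c(-1, 1) * half
  if (is.finite(digits)) b <- round(b, digits)
  b
}
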