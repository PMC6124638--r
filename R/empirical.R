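#' Elicit a prior variance from an observed pleiotropy band
#'
#' Converts a statement of the form "about \code{coverage} of plausible
#' pleiotropic effects lie within \eqn{\pm} \code{bandHalfwidth}" into
#' the variance of a normal prior centred at the stated mean:
#' \deqn{\sigma^2 = (bandHalfwidth / z_{(1+coverage)/2})^2.}
#' A band of \eqn{\pm 0.05} at 95\% coverage — the spread of observed
#' secondary-phenotype associations in the urate example — gives
#' \eqn{6.508 \times 10^{-4}}.
#'
#' @param bandHalfwidth half-width of the effect band (>= 0, outcome
#'   units, e.g. log-odds).
#' @param coverage prior mass to place inside the band, in (0, 1).
#' @return the prior variance (scalar).
#' @examples
#' elicitPriorVariance(0.05, 0.95)  # 6.508e-4
#' @export
elicitPriorVariance <- function(bandHalfwidth, coverage = 0.95) {
  if (bandHalfwidth < 0) stop("bandHalfwidth must be >= 0")
  if (!(coverage > 0 && coverage < 1)) {
    stop("coverage must lie in (0, 1)")
  }
  (bandHalfwidth / qnorm((1 + coverage) / 2))^2
}

#' Summarize observed pleiotropy across secondary phenotypes
#'
#' Takes a long table of per-SNP associations with secondary (potential
#' pleiotropic-pathway) phenotypes and summarizes the magnitude and
#' balance of observed pleiotropy: the fraction of effects inside a
#' stated band, the effect range, a symmetric-balance summary, and the
#' entries reaching genome-wide significance (p < 5e-8 by default),
#' which identify SNPs with clear pleiotropic signals.
#'
#' @param table data.frame with columns \code{snp}, \code{phenotype},
#'   \code{effect}, and \code{se} and/or \code{p} (a missing \code{p}
#'   is filled from the two-sided normal test of \code{effect/se}).
#' @param band half-width of the reporting band (default 0.05).
#' @param pThreshold genome-wide significance threshold (default 5e-8).
#' @return a list of class \code{"pleiotropyProfile"}: \code{nEntries},
#'   \code{band}, \code{fracWithinBand}, \code{range}, \code{meanEffect},
#'   \code{sharePositive}, \code{flagged} (the significant subset of the
#'   table) and \code{flaggedSNPs}.
#' @export
pleiotropyProfile <- function(table, band = 0.05, pThreshold = 5e-8) {
  need <- c("snp", "phenotype", "effect")
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (!"p" %in% names(table)) {
    if (!"se" %in% names(table)) {
      stop("missing required column(s): se or p")
    }
    table$p <- 2 * pnorm(-abs(table$effect / table$se))
  }
  flagged <- table[!is.na(table$p) & table$p < pThreshold, , drop = FALSE]
  structure(list(
    nEntries = nrow(table),
    band = band,
    fracWithinBand = mean(abs(table$effect) <= band),
    range = range(table$effect),
    meanEffect = mean(table$effect),
    sharePositive = mean(table$effect > 0),
    flagged = flagged,
    flaggedSNPs = unique(flagged$snp)
  ), class = "pleiotropyProfile")
}

#' @export
print.pleiotropyProfile <- function(x, ...) {
  cat(sprintf("Pleiotropy profile over %d SNP-phenotype associations\n",
              x$nEntries))
  cat(sprintf("  %.1f%% of effects within +/- %g; range (%.3g, %.3g)\n",
              100 * x$fracWithinBand, x$band, x$range[1], x$range[2]))
  cat(sprintf("  balance: mean effect %.4g, %.1f%% positive\n",
              x$meanEffect, 100 * x$sharePositive))
  if (length(x$flaggedSNPs)) {
    cat("  genome-wide significant signals in: ",
        paste(x$flaggedSNPs, collapse = ", "), "\n", sep = "")
  } else {
    cat("  no genome-wide significant signals\n")
  }
  invisible(x)
}

#' Fit all estimators on one empirical dataset
#'
#' Fits IVW, MR-Egger and the weighted median once, and the Bayesian
#' MR-Egger under each supplied prior, returning a report table in the
#' layout of a sensitivity analysis over intercept priors: one row per
#' method (or method x prior) with intercept and slope estimates and
#' intervals. With \code{exponentiate = TRUE} (for a binary outcome
#' analysed on the log-odds scale) point estimates and interval bounds
#' are reported as odds ratios.
#'
#' @param data an [MRSummary-class] object.
#' @param priors list of [MRPrior-class] objects for the BMRE rows; may
#'   be empty.
#' @param exponentiate report odds ratios instead of log-odds.
#' @param ciLevel interval level.
#' @param nBoot,seed weighted-median bootstrap controls.
#' @return a data.frame, one row per method/prior, with columns as in
#'   \code{as.data.frame(<MREstimate>)} plus \code{prior}.
#' @export
runEmpiricalAnalysis <- function(data, priors = list(),
                                 exponentiate = FALSE, ciLevel = 0.95,
                                 nBoot = 1000, seed = NULL) {
  fits <- list(
    cbind(prior = NA_character_,
          as.data.frame(fitIVW(data, ciLevel), exponentiate = exponentiate)),
    cbind(prior = NA_character_,
          as.data.frame(fitMREgger(data, ciLevel),
                        exponentiate = exponentiate))
  )
  labels <- names(priors)
  if (is.null(labels) && length(priors)) {
    labels <- vapply(priors, function(p) {
      sprintf("muPhi=%g,varPhi=%g", p@muPhi, p@varPhi)
    }, character(1))
  }
  for (i in seq_along(priors)) {
    fits[[length(fits) + 1L]] <- cbind(
      prior = labels[i],
      as.data.frame(fitBayesMREgger(data, priors[[i]], ciLevel),
                    exponentiate = exponentiate)
    )
  }
  fits[[length(fits) + 1L]] <- cbind(
    prior = NA_character_,
    as.data.frame(
      fitWeightedMedian(data, nBoot = nBoot, seed = seed,
                        ciLevel = ciLevel),
      exponentiate = exponentiate
    )
  )
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  out[, c("method", "prior",
          setdiff(names(out), c("method", "prior")))]
}
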