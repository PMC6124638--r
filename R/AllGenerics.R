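#' Orient instruments so that all exposure effects are non-negative
#'
#' The Egger regression is not invariant to the arbitrary choice of
#' effect allele: flipping an allele changes the sign of both
#' \eqn{\hat\alpha_j} and \eqn{\hat\beta_j}. The conventional
#' orientation recodes every SNP so that its exposure effect is
#' non-negative, flipping the outcome effect along with it. IVW and the
#' ratio-based weighted median are unaffected; MR-Egger and Bayesian
#' MR-Egger require it.
#'
#' @param data an [MRSummary-class] object.
#' @return an [MRSummary-class] with all \code{alpha >= 0}; idempotent.
#' @examples
#' d <- MRSummary(alpha = c(-1, 2), seAlpha = c(0, 0),
#'                beta = c(0.5, 1), seBeta = c(1, 1))
#' alphaHat(orientInstruments(d))  # 1 2
#' @export
setGeneric("orientInstruments", function(data) {
  standardGeneric("orientInstruments")
})

#' Outcome-effect weight matrix
#'
#' Builds the sampling variance-covariance matrix of the SNP-outcome
#' effects, \eqn{\Omega_{jk} = \hat\sigma_{\beta j} \hat\sigma_{\beta k}
#' \rho_{jk}}; diagonal \eqn{\hat\sigma^2_{\beta j}} for independent
#' SNPs. Its inverse supplies the generalized-least-squares weights of
#' every regression-based estimator.
#'
#' @param data an [MRSummary-class] object.
#' @return a symmetric positive-definite J x J matrix.
#' @export
setGeneric("buildWeightMatrix", function(data) {
  standardGeneric("buildWeightMatrix")
})

#' @rdname MRSummary-accessors
#' @export
setGeneric("nInstruments", function(object) standardGeneric("nInstruments"))

#' @rdname MRSummary-accessors
#' @export
setGeneric("alphaHat", function(object) standardGeneric("alphaHat"))

#' @rdname MRSummary-accessors
#' @export
setGeneric("betaHat", function(object) standardGeneric("betaHat"))

#' @rdname MRSummary-accessors
#' @export
setGeneric("seAlpha", function(object) standardGeneric("seAlpha"))

#' @rdname MRSummary-accessors
#' @export
setGeneric("seBeta", function(object) standardGeneric("seBeta"))

#' @rdname MREstimate-accessors
#' @export
setGeneric("slope", function(object) standardGeneric("slope"))

#' @rdname MREstimate-accessors
#' @export
setGeneric("slopeScale", function(object) standardGeneric("slopeScale"))

#' @rdname MREstimate-accessors
#' @export
setGeneric("intercept", function(object) standardGeneric("intercept"))

#' @rdname MREstimate-accessors
#' @export
setGeneric("interceptScale", function(object) standardGeneric("interceptScale"))

#' @rdname MREstimate-accessors
#' @export
setGeneric("slopeInterval", function(object) standardGeneric("slopeInterval"))

#' @rdname MREstimate-accessors
#' @export
setGeneric("interceptInterval", function(object) {
  standardGeneric("interceptInterval")
})

#' @rdname MREstimate-accessors
#' @export
setGeneric("rejectSlope", function(object) standardGeneric("rejectSlope"))

#' @rdname MREstimate-accessors
#' @export
setGeneric("rejectIntercept", function(object) {
  standardGeneric("rejectIntercept")
})
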