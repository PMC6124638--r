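#' Construct an MRSummary object
#'
#' @param alpha,seAlpha SNP-exposure effects and their standard errors.
#' @param beta,seBeta SNP-outcome effects and their standard errors.
#' @param snp optional instrument identifiers (default \code{snp1..snpJ}).
#' @param corr optional J x J between-SNP correlation matrix; identity
#'   (independent SNPs) when omitted.
#' @return an [MRSummary-class] object.
#' @examples
#' MRSummary(alpha = c(1, 2), seAlpha = c(0.1, 0.1),
#'           beta = c(0.5, 1), seBeta = c(1, 1))
#' @export
MRSummary <- function(alpha, seAlpha, beta, seBeta,
                      snp = paste0("snp", seq_along(alpha)),
                      corr = NULL) {
  J <- length(alpha)
  if (is.null(corr)) corr <- diag(J)
  new("MRSummary",
    snp = as.character(snp),
    alpha = as.numeric(alpha), seAlpha = as.numeric(seAlpha),
    beta = as.numeric(beta), seBeta = as.numeric(seBeta),
    corr = as.matrix(corr)
  )
}

#' Accessors for MRSummary objects
#'
#' @param object an [MRSummary-class] object.
#' @return \code{nInstruments}: the number of SNPs J; the others: the
#'   corresponding per-SNP vector.
#' @name MRSummary-accessors
NULL

#' @rdname MRSummary-accessors
#' @export
setMethod("nInstruments", "MRSummary", function(object) length(object@snp))

#' @rdname MRSummary-accessors
#' @export
setMethod("alphaHat", "MRSummary", function(object) object@alpha)

#' @rdname MRSummary-accessors
#' @export
setMethod("betaHat", "MRSummary", function(object) object@beta)

#' @rdname MRSummary-accessors
#' @export
setMethod("seAlpha", "MRSummary", function(object) object@seAlpha)

#' @rdname MRSummary-accessors
#' @export
setMethod("seBeta", "MRSummary", function(object) object@seBeta)

setMethod("show", "MRSummary", function(object) {
  J <- nInstruments(object)
  cat(sprintf("MRSummary with %d instrument%s\n", J, if (J == 1) "" else "s"))
  if (J > 0) {
    df <- as.data.frame(object)
    print(utils::head(df, 6), row.names = FALSE)
    if (J > 6) cat(sprintf("... and %d more SNPs\n", J - 6))
  }
  indep <- J == 0 || max(abs(object@corr - diag(J))) < 1e-12
  cat(if (indep) "independent SNPs (identity correlation)\n"
      else "user-supplied between-SNP correlation\n")
  invisible(NULL)
})

#' @describeIn MRSummary-accessors coerce to a data.frame with columns
#'   snp, alpha, se_alpha, beta, se_beta.
#' @param x an [MRSummary-class] object.
#' @param row.names,optional,... passed on conventionally; unused.
#' @export
as.data.frame.MRSummary <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  data.frame(
    snp = x@snp, alpha = x@alpha, se_alpha = x@seAlpha,
    beta = x@beta, se_beta = x@seBeta,
    stringsAsFactors = FALSE
  )
}

setMethod("as.data.frame", "MRSummary", as.data.frame.MRSummary)

#' @rdname orientInstruments
setMethod("orientInstruments", "MRSummary", function(data) {
  if (any(data@alpha == 0)) {
    warning("some alpha are exactly 0: the per-SNP ratio is undefined ",
            "for the weighted median (Egger regression is still defined)")
  }
  flip <- data@alpha < 0
  if (!any(flip)) return(data)
  out <- data
  out@alpha[flip] <- -out@alpha[flip]
  out@beta[flip] <- -out@beta[flip]
  out
})

#' @rdname buildWeightMatrix
setMethod("buildWeightMatrix", "MRSummary", function(data) {
  Omega <- tcrossprod(data@seBeta) * data@corr
  ev <- eigen(Omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("weight matrix is not positive definite: ",
         "check the between-SNP correlation matrix")
  }
  Omega
})

#' Read and write summary statistics as delimited text
#'
#' \code{readMRSummary} reads a TSV (or CSV) with header columns
#' \code{snp}, \code{alpha}, \code{se_alpha}, \code{beta},
#' \code{se_beta}; \code{mapping} renames foreign headers, e.g. a
#' supplementary table with columns \code{rsid}, \code{beta_exposure},
#' \code{se_exposure}, \code{beta_outcome}, \code{se_outcome} is read
#' with \code{mapping = c(snp = "rsid", alpha = "beta_exposure",
#' se_alpha = "se_exposure", beta = "beta_outcome", se_beta =
#' "se_outcome")}. An optional square correlation matrix, keyed by SNP
#' order, is read from \code{corrFile}.
#'
#' @param file path to the delimited file.
#' @param sep field separator; \code{"\t"} default, \code{","} accepted.
#' @param mapping named character vector mapping canonical column names
#'   to the file's headers.
#' @param corrFile optional path to a J x J correlation matrix TSV
#'   (no header), rows/columns in the SNP order of \code{file}.
#' @return \code{readMRSummary}: an [MRSummary-class] object.
#' @export
readMRSummary <- function(file, sep = "\t", mapping = NULL, corrFile = NULL) {
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("snp", "alpha", "se_alpha", "beta", "se_beta")
  if (!is.null(mapping)) {
    for (canon in names(mapping)) {
      if (!mapping[[canon]] %in% names(df)) {
        stop("mapped column '", mapping[[canon]], "' not found in ", file)
      }
      names(df)[names(df) == mapping[[canon]]] <- canon
    }
  }
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  corr <- NULL
  if (!is.null(corrFile)) {
    corr <- as.matrix(utils::read.table(corrFile, header = FALSE, sep = sep))
    dimnames(corr) <- NULL
  }
  MRSummary(snp = df$snp, alpha = df$alpha, seAlpha = df$se_alpha,
            beta = df$beta, seBeta = df$se_beta, corr = corr)
}

#' @rdname readMRSummary
#' @param data an [MRSummary-class] object to write.
#' @return \code{writeMRSummary}: the path, invisibly.
#' @export
writeMRSummary <- function(data, file, sep = "\t") {
  utils::write.table(as.data.frame(data), file, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}
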