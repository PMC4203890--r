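#' SampleBaseline: the balanced-state anchor of a tumor sample
#'
#' Holds the coordinates of the balanced (heterozygous, copy-neutral) state in
#' (folded BAF, LRR) space, the noise scales estimated from the baseline
#' cluster, and the sample-level context quantities used by the line-selection
#' criterion: the sample-wide aneuploid genome proportion \code{pS} and the
#' genome-average \code{ploidy}.
#'
#' @slot x0 numeric, folded-BAF coordinate of the balanced state.
#' @slot y0 numeric, LRR coordinate of the balanced state.
#' @slot sdBaf,numeric positive noise scale of segment-level folded BAF.
#' @slot sdLrr numeric, positive noise scale of segment-level LRR.
#' @slot pS numeric in [0,1], sample-wide aneuploid genome proportion.
#' @slot ploidy numeric > 0, genome-average copy number.
#' @slot doubled logical, whether the baseline was re-interpreted as a
#'   genome-doubled (2,4) state.
#'
#' @export
setClass("SampleBaseline",
  representation(
    x0 = "numeric", y0 = "numeric",
    sdBaf = "numeric", sdLrr = "numeric",
    pS = "numeric", ploidy = "numeric",
    doubled = "logical"
  ),
  prototype(x0 = 0, y0 = 0, sdBaf = 0.01, sdLrr = 0.04,
            pS = 0, ploidy = 2, doubled = FALSE)
)

setValidity("SampleBaseline", function(object) {
  msg <- character()
  if (length(object@sdBaf) != 1L || !is.finite(object@sdBaf) || object@sdBaf <= 0)
    msg <- c(msg, "sdBaf must be a single positive finite number")
  if (length(object@sdLrr) != 1L || !is.finite(object@sdLrr) || object@sdLrr <= 0)
    msg <- c(msg, "sdLrr must be a single positive finite number")
  if (!is.finite(object@x0) || !is.finite(object@y0))
    msg <- c(msg, "x0 and y0 must be finite")
  if (object@pS < 0 || object@pS > 1)
    msg <- c(msg, "pS must lie in [0,1]")
  if (object@ploidy <= 0)
    msg <- c(msg, "ploidy must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a SampleBaseline
#'
#' @param x0,y0 balanced-state coordinates in (folded BAF, LRR) space.
#' @param sdBaf,sdLrr segment-level noise scales (must be positive).
#' @param pS sample-wide aneuploid genome proportion.
#' @param ploidy genome-average copy number.
#' @param doubled logical flag for a genome-doubled baseline.
#' @return A [SampleBaseline-class] object.
#' @export
SampleBaseline <- function(x0 = 0, y0 = 0, sdBaf = 0.01, sdLrr = 0.04,
                           pS = 0, ploidy = 2, doubled = FALSE) {
  new("SampleBaseline", x0 = x0, y0 = y0, sdBaf = sdBaf, sdLrr = sdLrr,
      pS = pS, ploidy = ploidy, doubled = doubled)
}

setMethod("show", "SampleBaseline", function(object) {
  cat("SampleBaseline\n")
  cat(sprintf("  origin (x0, y0): (%.4f, %.4f)%s\n", object@x0, object@y0,
              if (object@doubled) "  [genome-doubled]" else ""))
  cat(sprintf("  noise (sdBaf, sdLrr): (%.4f, %.4f)\n",
              object@sdBaf, object@sdLrr))
  cat(sprintf("  sample AGP pS: %.3f   ploidy: %.3f\n",
              object@pS, object@ploidy))
  invisible(NULL)
})

#' @describeIn SampleBaseline criterion-(a) distance threshold
#'   \eqn{2\sqrt{sd_{BAF}^2 + sd_{LRR}^2}} (times the configured multiplier).
#' @param object a `SampleBaseline`.
#' @param multiplier threshold multiplier (default 2).
#' @export
baselineThreshold <- function(object, multiplier = 2) {
  multiplier * sqrt(object@sdBaf^2 + object@sdLrr^2)
}

#' ClonalModelFit: fitted description of an sAGP or CCF spectrum
#'
#' Result container for the clonal-structure stage: either a single Gaussian
#' peak over a uniform background ("unimodal_uniform", Model-1) or a
#' Dirichlet-process Gaussian mixture ("dp_mixture", Model-2), with the BIC
#' values used for selection.
#'
#' @slot model character, "unimodal_uniform" or "dp_mixture".
#' @slot A numeric, uniform-component weight of Model-1.
#' @slot mu,sigma numeric, Model-1 peak location and width.
#' @slot clusters data.frame with columns weight, mean, sd (Model-2 peaks).
#' @slot loglik,bic numeric, log-likelihood and BIC of the chosen model.
#' @slot bicAll named numeric, BIC of both candidate models.
#' @slot nPeaks integer, number of peaks with weight above the reporting
#'   threshold (Model-1 reports 1).
#' @slot converged logical, Gibbs-chain stability heuristic for Model-2.
#'
#' @export
setClass("ClonalModelFit",
  representation(
    model = "character",
    A = "numeric", mu = "numeric", sigma = "numeric",
    clusters = "data.frame",
    loglik = "numeric", bic = "numeric", bicAll = "numeric",
    nPeaks = "integer", converged = "logical"
  ),
  prototype(model = "unimodal_uniform", A = NA_real_, mu = NA_real_,
            sigma = NA_real_, clusters = data.frame(),
            loglik = NA_real_, bic = NA_real_, bicAll = numeric(),
            nPeaks = 1L, converged = TRUE)
)

setValidity("ClonalModelFit", function(object) {
  if (!object@model %in% c("unimodal_uniform", "dp_mixture"))
    return("model must be 'unimodal_uniform' or 'dp_mixture'")
  if (object@model == "dp_mixture" && nrow(object@clusters) > 0) {
    w <- object@clusters$weight
    if (any(w < 0) || abs(sum(w) - 1) > 1e-6)
      return("cluster weights must be non-negative and sum to 1")
  }
  TRUE
})

setMethod("show", "ClonalModelFit", function(object) {
  cat("ClonalModelFit:", object@model, "\n")
  if (object@model == "unimodal_uniform") {
    cat(sprintf("  uniform weight A = %.3f, peak mu = %.3f (sd %.3f)\n",
                object@A, object@mu, object@sigma))
  } else {
    cat(sprintf("  %d peak(s):\n", object@nPeaks))
    cl <- object@clusters
    for (i in seq_len(nrow(cl)))
      cat(sprintf("    weight %.3f  mean %.3f  sd %.4f\n",
                  cl$weight[i], cl$mean[i], cl$sd[i]))
  }
  cat(sprintf("  loglik %.2f  BIC %.2f\n", object@loglik, object@bic))
  invisible(NULL)
})

#' @describeIn ClonalModelFit number of reported peaks.
#' @param object a `ClonalModelFit`.
#' @export
nPeaks <- function(object) object@nPeaks

#' @describeIn ClonalModelFit peak table (weight, mean, sd).
#' @export
clusterTable <- function(object) {
  if (object@model == "unimodal_uniform")
    data.frame(weight = 1 - object@A, mean = object@mu, sd = object@sigma)
  else
    object@clusters
}
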