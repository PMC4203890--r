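# Macroscopic clonal structure: uniform+Gaussian (Model-1) versus a
# Dirichlet-process Gaussian mixture (Model-2), selected by BIC.

#' Filter an sAGP (or CCF) vector for clonal-structure fitting
#'
#' Bins meeting the euploid rule (`medFbaf <= 0.04` and `|medLrr| <= 0.16`)
#' get sAGP 0; bins with missing sAGP are dropped; values at or below
#' `minValue` are removed so that near-zero estimates do not dominate the
#' spectrum. Samples retaining fewer than `minBins` values are flagged
#' unanalyzable.
#'
#' @param segments GRanges with `medFbaf`, `medLrr`, `sAGP` columns, or a
#'   bare numeric vector (e.g. CCF values; the euploid rule then does not
#'   apply).
#' @param minValue removal threshold (default 0.05).
#' @param minBins minimum surviving values (default 50).
#' @param fbafEuploid,lrrEuploid euploid-call thresholds (defaults 0.04,
#'   0.16).
#' @return list with numeric `Y`, `n`, and logical `analyzable`.
#' @export
prepareSagpVector <- function(segments, minValue = 0.05, minBins = 50L,
                              fbafEuploid = 0.04, lrrEuploid = 0.16) {
  if (is.numeric(segments)) {
    y <- segments[!is.na(segments)]
  } else {
    y <- mcols(segments)$sAGP
    eu <- !is.na(mcols(segments)$medFbaf) &
      abs(mcols(segments)$medFbaf) <= fbafEuploid &
      abs(mcols(segments)$medLrr) <= lrrEuploid
    y[eu] <- 0
    y <- y[!is.na(y)]
  }
  y <- y[y > minValue]
  list(Y = y, n = length(y), analyzable = length(y) >= minBins)
}

#' Fit the uniform-plus-Gaussian model (Model-1)
#'
#' Maximizes \eqn{l = \sum_i \ln(A/\mathrm{range}(Y) + (1-A)\,
#' N(y_i; \mu, \sigma))} with `A` and `mu` constrained to (0,1) and
#' `sigma > 0`, by multi-start bounded optimization (starts: `mu` at the
#' quartiles of Y, `A` in {0.1, 0.5, 0.9}).
#'
#' @param Y numeric vector from [prepareSagpVector()].
#' @return list with `A`, `mu`, `sigma`, `loglik` (NULL if every start
#'   failed).
#' @export
fitModel1 <- function(Y) {
  rng <- diff(range(Y))
  if (rng <= 0) stop("degenerate input: range(Y) is zero")
  negll <- function(par) {
    A <- par[1L]; mu <- par[2L]; sg <- exp(par[3L])
    -sum(log(A / rng + (1 - A) * dnorm(Y, mu, sg)))
  }
  starts <- expand.grid(A = c(0.1, 0.5, 0.9),
                        mu = unname(quantile(Y, c(0.25, 0.5, 0.75))),
                        lsg = log(c(0.02, max(sd(Y), 1e-3))))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(as.numeric(starts[i, ]), negll, method = "L-BFGS-B",
            lower = c(1e-6, 1e-6, log(1e-4)),
            upper = c(1 - 1e-6, 1 - 1e-6, log(2))),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) {
    warning("Model-1 optimization failed on all starts")
    return(NULL)
  }
  list(A = best$par[1L], mu = best$par[2L], sigma = exp(best$par[3L]),
       loglik = -best$value)
}

#' Default priors for the DP mixture
#'
#' Diffuse, data-anchored settings: base-measure location at `mean(Y)`,
#' inverse-gamma scale from `var(Y)`, unit Gamma priors on the precision
#' scale `k0` and the DP concentration.
#'
#' @param Y data vector.
#' @return named list of hyperparameters and MCMC settings.
#' @export
dpPriorConfig <- function(Y) {
  list(mu1 = mean(Y), k0 = 1, nu1 = 4, psi1 = max(stats::var(Y), 1e-6),
       tau1 = 1, tau2 = 1, a0 = 1, b0 = 1,
       nIter = 10000L, nBurn = 2000L, nThin = 5L, alphaFix = 0)
}

#' Fit the Dirichlet-process Gaussian mixture (Model-2)
#'
#' Gibbs sampling for a DP mixture of normals with a normal/inverse-gamma
#' base measure (the 1-D specialization of a normal/inverse-Wishart):
#' cluster assignments by the Chinese-restaurant scheme with collapsed
#' cluster parameters, explicit conjugate draws of per-cluster means and
#' variances, a Gamma update of the base-measure precision scale `k0`, and
#' an Escobar-West update of the concentration. The reported clustering is
#' the posterior-mode number of occupied clusters, represented by the
#' retained sample of that size with the highest joint density
#' (classification likelihood, parameter priors and partition prior); the
#' log-likelihood reported for model selection is the mixture log-density of
#' the data at that point estimate.
#'
#' @param Y numeric vector.
#' @param priors list as from [dpPriorConfig()] (set `alphaFix > 0` to pin
#'   the concentration).
#' @param minWeight cluster weight below which a cluster is not counted as a
#'   peak (default 0.05).
#' @param seed integer seed for the chain (default 1).
#' @return list with `clusters` (data.frame weight/mean/sd), `loglik`,
#'   `nPeaks`, `converged`.
#' @export
fitModel2DP <- function(Y, priors = NULL, minWeight = 0.05,
                        seed = 1L) {
  # force and sort the input (priors included) before seeding: the fit is
  # then exchangeable in Y's order and independent of the caller's RNG use
  Y <- sort(Y)
  if (is.null(priors)) priors <- dpPriorConfig(Y)
  set.seed(seed)
  res <- .dpGibbsCpp(Y, priors$mu1, priors$k0, priors$nu1, priors$psi1,
                     priors$tau1, priors$tau2, priors$a0, priors$b0,
                     as.integer(priors$nIter), as.integer(priors$nBurn),
                     as.integer(priors$nThin), priors$alphaFix)
  st <- res$state
  ord <- order(st$mean)
  cl <- data.frame(weight = st$weight[ord], mean = st$mean[ord],
                   sd = st$sd[ord])
  # BIC likelihood: mixture log-density of Y at the point estimate
  dens <- rowSums(mapply(function(w, m, s) w * dnorm(Y, m, s),
                         cl$weight, cl$mean, cl$sd))
  loglik <- sum(log(pmax(dens, .Machine$double.xmin)))
  # stability heuristic: modal K must dominate the last quarter of the chain
  kTr <- res$kTrace
  lastQ <- kTr[seq.int(floor(3 * length(kTr) / 4) + 1L, length(kTr))]
  converged <- mean(lastQ == res$kMode) >= 0.5
  if (!converged)
    warning("occupied-cluster count not stabilized over the last quarter ",
            "of the chain")
  list(clusters = cl, loglik = loglik,
       nPeaks = sum(cl$weight >= minWeight), converged = converged)
}

#' Select between Model-1 and Model-2 by BIC
#'
#' `BIC = k ln(n) - 2 loglik` with `k = 3` for the uniform-plus-Gaussian
#' model and `k = 7` for the DP mixture (its hyperparameter count); the
#' smaller BIC wins.
#'
#' @param fit1 result of [fitModel1()] (or NULL).
#' @param fit2 result of [fitModel2DP()] (or NULL).
#' @param n number of observations.
#' @return A [ClonalModelFit-class].
#' @export
selectModel <- function(fit1, fit2, n) {
  bic1 <- if (!is.null(fit1)) 3 * log(n) - 2 * fit1$loglik else Inf
  bic2 <- if (!is.null(fit2)) 7 * log(n) - 2 * fit2$loglik else Inf
  if (is.null(fit1) && is.null(fit2)) stop("no model fit available")
  if (is.null(fit1) || is.null(fit2))
    warning("one model fit unavailable; selecting the other by default")
  bicAll <- c(unimodal_uniform = bic1, dp_mixture = bic2)
  if (bic1 <= bic2) {
    new("ClonalModelFit", model = "unimodal_uniform", A = fit1$A,
        mu = fit1$mu, sigma = fit1$sigma, loglik = fit1$loglik,
        bic = bic1, bicAll = bicAll, nPeaks = 1L, converged = TRUE)
  } else {
    new("ClonalModelFit", model = "dp_mixture", clusters = fit2$clusters,
        loglik = fit2$loglik, bic = bic2, bicAll = bicAll,
        nPeaks = as.integer(fit2$nPeaks), converged = fit2$converged)
  }
}

#' Fit the clonal structure of a sample
#'
#' Convenience wrapper: filter the sAGP (or CCF) spectrum, fit both models,
#' and select by BIC.
#'
#' @inheritParams prepareSagpVector
#' @param seed chain seed for the DP fit.
#' @param priors optional DP prior list.
#' @return A [ClonalModelFit-class], or NULL (with a warning) if the sample
#'   has too few informative values.
#' @export
fitClonalStructure <- function(segments, minValue = 0.05, minBins = 50L,
                               seed = 1L, priors = NULL) {
  prep <- prepareSagpVector(segments, minValue, minBins)
  if (!prep$analyzable) {
    warning("only ", prep$n, " informative values (< ", minBins,
            "); clonal structure not fitted")
    return(NULL)
  }
  Y <- prep$Y
  if (is.null(priors)) priors <- dpPriorConfig(Y)
  fit1 <- fitModel1(Y)
  fit2 <- fitModel2DP(Y, priors, seed = seed)
  selectModel(fit1, fit2, length(Y))
}
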