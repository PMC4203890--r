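# sAGP inference: assign each segment to a canonical (n_b, n_t) mixing line
# anchored at the sample baseline, and estimate the mixing fraction p.

#' Candidate copy-number states
#'
#' Enumerates the canonical states `(n_b, n_t)` with `0 <= n_b <= n_t/2`,
#' `1 <= n_t <= maxNt`, excluding the euploid reference (1, 2).
#'
#' @param maxNt maximum total copy number (default 6).
#' @return data.frame with columns `nB`, `nT`.
#' @export
candidateStates <- function(maxNt = 6L) {
  st <- do.call(rbind, lapply(seq_len(maxNt), function(nt)
    data.frame(nB = 0:(nt %/% 2L), nT = nt)))
  st[!(st$nB == 1L & st$nT == 2L), , drop = FALSE]
}

#' Theoretical position of a copy state on its canonical line
#'
#' Under regional two-way mixing of an aneuploid population (fraction `p`,
#' state `(nB, nT)`) with the euploid population, the expected signals are
#' \deqn{fBAF = |(p n_b + 1 - p)/(p n_t + 2(1-p)) - 0.5| + x_0}
#' \deqn{LRR = \log_2(p n_t + 2(1-p)) - 1 + y_0.}
#' As `p` runs over [0,1] the point traces the state's canonical line,
#' starting at the balanced origin `(x0, y0)`.
#'
#' @param nB,nT minor and total copy number of the aneuploid state.
#' @param p mixing fraction(s) in [0,1]; vectorized.
#' @param baseline a [SampleBaseline-class] (default: origin at (0,0)).
#' @return A list with numeric vectors `baf` (folded BAF) and `lrr`.
#' @export
canonicalPosition <- function(nB, nT, p, baseline = SampleBaseline()) {
  stopifnot(all(p >= 0 & p <= 1))
  nbar <- p * nT + 2 * (1 - p)
  if (any(nbar <= 0)) stop("degenerate mixture: average copy number is zero")
  list(baf = abs((p * nB + 1 - p) / nbar - 0.5) + baseline@x0,
       lrr = log2(nbar) - 1 + baseline@y0)
}

# squared distance from (fb, lr) to the state's canonical point at p
.canonDist2 <- function(p, nB, nT, fb, lr, baseline, wB = 1, wL = 1) {
  pos <- canonicalPosition(nB, nT, p, baseline)
  ((pos$baf - fb) / wB)^2 + ((pos$lrr - lr) / wL)^2
}

# closest point on one canonical line: 101-point grid scan then golden-section
# refinement (the fold in BAF creates local minima)
.fitLine <- function(nB, nT, fb, lr, baseline, wB = 1, wL = 1) {
  grid <- seq(0, 1, length.out = 101L)
  d2 <- .canonDist2(grid, nB, nT, fb, lr, baseline, wB, wL)
  i <- which.min(d2)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(101L, i + 1L)]
  opt <- optimize(.canonDist2, c(lo, hi), nB = nB, nT = nT, fb = fb, lr = lr,
                  baseline = baseline, wB = wB, wL = wL, tol = 1e-6)
  if (opt$objective < d2[i]) list(p = opt$minimum, dist = sqrt(opt$objective))
  else list(p = grid[i], dist = sqrt(d2[i]))
}

#' Mean copy number of a partially mixed sCNA
#'
#' @param p sAGP in [0,1].
#' @param nT total copies of the aneuploid state.
#' @return `2(1-p) + nT*p`.
#' @export
meanCopyNumber <- function(p, nT) 2 * (1 - p) + nT * p

#' Estimate the sample baseline from segment summaries
#'
#' Locates the balanced (folded BAF near 0) segment cluster: among segments
#' with `medFbaf < 0.1`, the LRR kernel-density peak defines the cluster
#' center; segments within 3 robust SDs of the peak form the baseline
#' cluster. `(x0, y0)` are the cluster medians and `sdBaf`/`sdLrr` its
#' scatter (MAD x 1.4826, floored at `sdFloor`). `pS` and `ploidy` are
#' provisional (0 and 2) until [estimateGlobalContext()].
#'
#' @param segments GRanges with `medFbaf`, `medLrr` columns.
#' @param sdFloor lower bound on the noise scales (default 1e-3).
#' @param doublingCheck re-interpret the origin as a genome-doubled (2,4)
#'   state when that halves the aggregate line-fit residual (default FALSE;
#'   the balanced heterozygous state is assumed).
#' @return A [SampleBaseline-class].
#' @export
estimateBaseline <- function(segments, sdFloor = 1e-3,
                             doublingCheck = FALSE) {
  fb <- mcols(segments)$medFbaf
  lr <- mcols(segments)$medLrr
  ok <- !is.na(fb) & !is.na(lr)
  fb <- fb[ok]; lr <- lr[ok]
  if (length(fb) < 10L)
    stop("too few segments (", length(fb), ") to estimate a baseline")
  bal <- fb < 0.1
  if (!any(bal))
    stop("no balanced segment (medFbaf < 0.1): sample unanalyzable")
  lrBal <- lr[bal]
  peak <- if (length(lrBal) >= 3L) {
    d <- density(lrBal, bw = "nrd0")
    d$x[which.max(d$y)]
  } else median(lrBal)
  sdRob <- max(mad(lrBal, center = peak), sdFloor)
  cl <- bal
  cl[bal] <- abs(lrBal - peak) <= 3 * sdRob
  x0 <- median(fb[cl]); y0 <- median(lr[cl])
  sdBaf <- max(mad(fb[cl], constant = 1.4826), sdFloor)
  sdLrr <- max(mad(lr[cl], constant = 1.4826), sdFloor)
  bl <- SampleBaseline(x0 = x0, y0 = y0, sdBaf = sdBaf, sdLrr = sdLrr)
  if (doublingCheck) {
    alt <- SampleBaseline(x0 = x0, y0 = y0 - 1, sdBaf = sdBaf, sdLrr = sdLrr,
                          doubled = TRUE)
    resid <- function(b) {
      st <- candidateStates()
      sum(vapply(which(!cl), function(i) {
        min(vapply(seq_len(nrow(st)), function(j)
          .fitLine(st$nB[j], st$nT[j], fb[i], lr[i], b)$dist, 1))
      }, 1))
    }
    if (sum(!cl) > 0 && resid(alt) < 0.5 * resid(bl)) {
      message("baseline re-interpreted as genome-doubled (2,4) state")
      bl <- alt
    }
  }
  bl
}

#' Fit the sAGP of one segment
#'
#' Scans every candidate canonical line for the closest point to the
#' segment's `(medFbaf, medLrr)`. Criterion (a): lines whose minimized
#' distance is at most `2 sqrt(sdBaf^2 + sdLrr^2)` survive. Criterion (b):
#' among survivors, minimize `F = |meanCopy(state, p) - ploidy| + |pS - p|`
#' (ties: smaller residual, then lower total copy number). Segments inside
#' the euploid noise ellipse around the origin are called euploid (`p = 0`,
#' state (1,2)); segments with no surviving line fail the regional two-way
#' mixing hypothesis and return missing values.
#'
#' @param medFbaf,medLrr segment summaries.
#' @param baseline a [SampleBaseline-class] with `pS`/`ploidy` filled.
#' @param states candidate states as from [candidateStates()].
#' @param thresholdMultiplier criterion-(a) multiplier (default 2).
#' @param metric "euclidean" (default) or "standardized" (per-axis residuals
#'   divided by `sdBaf`/`sdLrr`; threshold then `thresholdMultiplier*sqrt(2)`).
#' @return list with `nB`, `nT`, `p`, `residual`, `nCandidates`.
#' @export
fitSAGP <- function(medFbaf, medLrr, baseline, states = candidateStates(),
                    thresholdMultiplier = 2, metric = c("euclidean",
                                                        "standardized"),
                    useContext = TRUE) {
  metric <- match.arg(metric)
  miss <- list(nB = NA_integer_, nT = NA_integer_, p = NA_real_,
               residual = NA_real_, nCandidates = 0L)
  if (is.na(medFbaf) || is.na(medLrr)) return(miss)
  if (metric == "euclidean") {
    wB <- 1; wL <- 1
    thr <- thresholdMultiplier * sqrt(baseline@sdBaf^2 + baseline@sdLrr^2)
  } else {
    wB <- baseline@sdBaf; wL <- baseline@sdLrr
    thr <- thresholdMultiplier * sqrt(2)
  }
  dOrigin <- sqrt(((medFbaf - baseline@x0) / wB)^2 +
                  ((medLrr - baseline@y0) / wL)^2)
  if (dOrigin <= thr)
    return(list(nB = 1L, nT = 2L, p = 0, residual = dOrigin,
                nCandidates = 1L))
  fits <- lapply(seq_len(nrow(states)), function(j)
    .fitLine(states$nB[j], states$nT[j], medFbaf, medLrr, baseline, wB, wL))
  dist <- vapply(fits, `[[`, 1, "dist")
  pHat <- vapply(fits, `[[`, 1, "p")
  surv <- which(dist <= thr)
  if (!length(surv)) return(miss)
  Fcrit <- if (useContext)
    abs(meanCopyNumber(pHat[surv], states$nT[surv]) - baseline@ploidy) +
      abs(baseline@pS - pHat[surv])
  else rep(0, length(surv))
  ord <- order(Fcrit, dist[surv], states$nT[surv])
  k <- surv[ord[1L]]
  list(nB = as.integer(states$nB[k]), nT = as.integer(states$nT[k]),
       p = pHat[k], residual = dist[k], nCandidates = length(surv))
}

#' Sample-wide AGP and ploidy from first-pass sAGP estimates
#'
#' `ploidy` is the segment-length-weighted mean of the mean copy number
#' (euploid segments contribute 2); `pS` is the mode (largest kernel-density
#' peak) of the sAGP distribution over sCNA segments.
#'
#' @param segments GRanges carrying first-pass `nT`, `sAGP` columns.
#' @return list with `pS` and `ploidy`.
#' @export
estimateGlobalContext <- function(segments) {
  p <- mcols(segments)$sAGP
  nT <- mcols(segments)$nT
  len <- as.numeric(width(segments))
  mc <- ifelse(is.na(p), 2, meanCopyNumber(p, ifelse(is.na(nT), 2L, nT)))
  ploidy <- sum(mc * len) / sum(len)
  pScna <- p[!is.na(p) & p > 0]
  pS <- if (!length(pScna)) 0
  else if (length(pScna) < 3L) median(pScna)
  else {
    d <- density(pScna, bw = "nrd0", from = 0, to = 1)
    d$x[which.max(d$y)]
  }
  list(pS = min(max(pS, 0), 1), ploidy = ploidy)
}

#' Estimate sAGP for every segment (two-pass)
#'
#' Pass 1 fits each segment with provisional context (`pS = 0`, `ploidy = 2`,
#' ties resolved by residual alone); [estimateGlobalContext()] then supplies
#' the sample-wide AGP and ploidy for the definitive pass 2.
#'
#' @param segments GRanges with `medFbaf`, `medLrr`.
#' @param baseline optional precomputed [SampleBaseline-class]; estimated
#'   from the segments when NULL.
#' @param maxNt maximum candidate total copy number (default 6).
#' @inheritParams fitSAGP
#' @return The input GRanges with columns `nB`, `nT`, `sAGP`, `residual`,
#'   `nCandidates` added, and the refined baseline in
#'   `metadata(.)$baseline`.
#' @export
estimateSAGP <- function(segments, baseline = NULL, maxNt = 6L,
                         thresholdMultiplier = 2,
                         metric = "euclidean") {
  if (is.null(baseline)) baseline <- estimateBaseline(segments)
  states <- candidateStates(maxNt)
  runPass <- function(bl, useContext = TRUE) {
    fits <- lapply(seq_along(segments), function(i)
      fitSAGP(mcols(segments)$medFbaf[i], mcols(segments)$medLrr[i], bl,
              states, thresholdMultiplier, metric, useContext = useContext))
    mcols(segments)$nB <<- vapply(fits, `[[`, 1L, "nB")
    mcols(segments)$nT <<- vapply(fits, `[[`, 1L, "nT")
    mcols(segments)$sAGP <<- vapply(fits, `[[`, 1, "p")
    mcols(segments)$residual <<- vapply(fits, `[[`, 1, "residual")
    mcols(segments)$nCandidates <<- vapply(fits, `[[`, 1L, "nCandidates")
  }
  runPass(baseline, useContext = FALSE)
  ctx <- estimateGlobalContext(segments)
  baseline@pS <- ctx$pS
  baseline@ploidy <- ctx$ploidy
  runPass(baseline)
  S4Vectors::metadata(segments)$baseline <- baseline
  segments
}
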