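# Synthetic tumors: mixed-clone sCNA segments with Gaussian BAF/LRR noise and
# scenario-constrained somatic read counts; scoring of the estimators.

.STATE_TABLE <- data.frame(
  type = c("deletion", "cnloh", "amplification", "balanced"),
  nB = c(0L, 0L, 1L, 2L),
  nT = c(1L, 2L, 3L, 4L),
  weight = c(2 / 7, 2 / 7, 2 / 7, 1 / 7))

#' Simulate a two-clone sCNA segment set
#'
#' Generates `nEuploid` euploid segments and `nScna` sCNA segments, the
#' latter split `domFraction` to a dominant clone (sAGP `pDom`) and the rest
#' to a minor clone (sAGP `pSub`). Copy states are drawn with weights 2/7
#' deletion (0,1), 2/7 CN-LOH (0,2), 2/7 amplification (1,3), 1/7 balanced
#' doubling (2,4). Observed segment summaries are
#' \deqn{fBAF = |0.5 - (p n_b + 1-p)/\bar n_t| + N(0, \sigma_{BAF})}
#' \deqn{LRR = \log_2 \bar n_t - 1 + N(0, \sigma_{LRR})}
#' with \eqn{\bar n_t = 2(1-p) + n_t p}. Segments are laid out in shuffled
#' order along one synthetic chromosome, `segLen` bp each.
#'
#' @param pDom,pSub dominant/minor clone sAGP (`pSub < pDom`; `pSub = 0`
#'   makes the minor-clone segments truly euploid).
#' @param nEuploid,nScna segment counts (defaults 200, 200).
#' @param domFraction fraction of sCNA segments in the dominant clone
#'   (default 2/3, i.e. 133 of 200).
#' @param sigmaBaf,sigmaLrr segment-level noise SDs (defaults 0.01, 0.04).
#' @param stateWeights optional length-4 weight vector over
#'   deletion/CN-LOH/amplification/balanced.
#' @param pRandom draw each sCNA's sAGP from U(0,1) instead of the two-clone
#'   values (used by the comparison protocol).
#' @param segLen segment length in bp (default 1e6).
#' @param seed integer seed (default 1).
#' @return GRanges with observed `medFbaf`, `medLrr`, `nSnps`, `unitKind`
#'   and truth columns `trueNb`, `trueNt`, `trueP`, `clone`. A segment whose
#'   true sAGP is 0 carries the euploid truth state (1,2).
#' @export
simulateSegments <- function(pDom = 0.9, pSub = 0.4, nEuploid = 200L,
                             nScna = 200L, domFraction = 2 / 3,
                             sigmaBaf = 0.01, sigmaLrr = 0.04,
                             stateWeights = NULL, pRandom = FALSE,
                             segLen = 1e6, seed = 1L) {
  stopifnot(pRandom || pSub < pDom)
  set.seed(seed)
  w <- if (is.null(stateWeights)) .STATE_TABLE$weight else stateWeights
  stopifnot(length(w) == 4L, abs(sum(w) - 1) < 1e-9)
  nDom <- round(domFraction * nScna)
  nSub <- nScna - nDom
  stIdx <- sample.int(4L, nScna, replace = TRUE, prob = w)
  nB <- c(rep(1L, nEuploid), .STATE_TABLE$nB[stIdx])
  nT <- c(rep(2L, nEuploid), .STATE_TABLE$nT[stIdx])
  p <- if (pRandom) c(rep(0, nEuploid), runif(nScna))
       else c(rep(0, nEuploid), rep(pDom, nDom), rep(pSub, nSub))
  clone <- c(rep("euploid", nEuploid), rep("dominant", if (pRandom) nScna
                                           else nDom),
             if (!pRandom) rep("minor", nSub))
  # a segment with p = 0 is observationally euploid
  nB[p == 0] <- 1L; nT[p == 0] <- 2L
  nbar <- meanCopyNumber(p, nT)
  fbaf <- abs(0.5 - (p * nB + 1 - p) / nbar) + rnorm(length(p), 0, sigmaBaf)
  lrr <- log2(nbar) - 1 + rnorm(length(p), 0, sigmaLrr)
  ord <- sample.int(length(p))
  if (length(p) * segLen > 2e9) segLen <- floor(2e9 / length(p))
  starts <- seq(1, by = segLen, length.out = length(p))
  gr <- GRanges("sim1", IRanges(starts, width = segLen),
                nSnps = 36L, medLrr = lrr[ord], medFbaf = fbaf[ord],
                unitKind = "scna",
                trueNb = nB[ord], trueNt = nT[ord], trueP = p[ord],
                clone = clone[ord])
  gr
}

#' Enumerate the dominant/minor sAGP validation grid
#'
#' `pDom` runs over `{step, 2*step, ..., 1}` and, for each, `pSub` over
#' `{0, step, ..., pDom - step}`. At the default step 0.1 this yields 55
#' pairs.
#'
#' @param step grid step (must divide 1; default 0.1).
#' @return data.frame with columns `pDom`, `pSub`.
#' @export
sagpGrid <- function(step = 0.1) {
  stopifnot(abs(1 / step - round(1 / step)) < 1e-9)
  do.call(rbind, lapply(seq(step, 1, by = step), function(pd)
    data.frame(pDom = pd, pSub = seq(0, pd - step, by = step))))
}

#' Simulate scenario-constrained somatic variants over a segment set
#'
#' Places `nSnv` variants uniformly over the genome by length (segments with
#' a missing sAGP estimate are excluded from hosting). A variant on euploid
#' territory draws its SAF from U(0, 0.5) with true CCF = 2*SAF. A variant
#' inside an sCNA draws its lineage scenario uniformly from the state's
#' admissible set, its SAF uniformly from that scenario's admissible
#' interval, and its true CCF from the scenario's CCF expression. Read
#' counts are `N ~ Poisson(coverage)` (zero depths redrawn) and
#' `S ~ Binomial(N, f)`.
#'
#' The host state and sAGP used are the *estimated* columns (`nB`, `nT`,
#' `sAGP`) when present — deliberately propagating upstream estimation error
#' into the CCF benchmark — falling back to the truth columns otherwise.
#'
#' @param segments GRanges from [simulateSegments()], normally after
#'   [estimateSAGP()].
#' @param nSnv number of variants (default 4000).
#' @param coverage mean read depth (default 50).
#' @param seed integer seed.
#' @return GRanges with `S`, `N`, `saf` and truth columns `trueF`,
#'   `trueCcf`, `trueScenario`, `hostClone`, `hostType`.
#' @export
simulateVariants <- function(segments, nSnv = 4000L, coverage = 50,
                             seed = 1L) {
  set.seed(seed)
  est <- all(c("nB", "nT", "sAGP") %in% names(mcols(segments)))
  hNb <- if (est) mcols(segments)$nB else mcols(segments)$trueNb
  hNt <- if (est) mcols(segments)$nT else mcols(segments)$trueNt
  hP <- if (est) mcols(segments)$sAGP else mcols(segments)$trueP
  hostable <- !is.na(hP)
  wLen <- as.numeric(width(segments)) * hostable
  seg <- sample.int(length(segments), nSnv, replace = TRUE,
                    prob = wLen / sum(wLen))
  pos <- start(segments)[seg] +
    floor(runif(nSnv) * as.numeric(width(segments)[seg]))
  f <- numeric(nSnv); ccf <- numeric(nSnv)
  scen <- character(nSnv)
  for (i in seq_len(nSnv)) {
    j <- seg[i]
    if (hP[j] <= 0 || (hNb[j] == 1L && hNt[j] == 2L)) {
      f[i] <- runif(1, 0, 0.5)
      ccf[i] <- 2 * f[i]
      scen[i] <- "euploid"
    } else {
      sc <- admissibleScenarios(hNb[j], hNt[j])
      scen[i] <- sample(sc, 1L)
      b <- safBounds(hNb[j], hNt[j], hP[j], scen[i])
      f[i] <- runif(1, b[1L], b[2L])
      ccf[i] <- ccfExpression(f[i], hNb[j], hNt[j], hP[j], scen[i])
    }
  }
  N <- rpois(nSnv, coverage)
  while (any(N < 1L)) N[N < 1L] <- rpois(sum(N < 1L), coverage)
  S <- rbinom(nSnv, N, f)
  type <- rep("euploid", nSnv)
  isS <- scen != "euploid"
  ty <- .STATE_TABLE$type[match(paste(hNb[seg], hNt[seg]),
                                paste(.STATE_TABLE$nB, .STATE_TABLE$nT))]
  ty[is.na(ty)] <- "other"
  type[isS] <- ty[isS]
  gr <- GRanges("sim1", IRanges(pos, width = 1L),
                S = S, N = N, saf = S / N,
                trueF = f, trueCcf = ccf, trueScenario = scen,
                hostClone = mcols(segments)$clone[seg],
                hostType = type)
  GenomicRanges::sort(gr)
}

#' Score sAGP estimates against simulation truth
#'
#' @param segments GRanges carrying both estimate (`nB`, `nT`, `sAGP`) and
#'   truth (`trueNb`, `trueNt`, `trueP`) columns.
#' @return data.frame, one row per clone stratum plus "all", with the copy-
#'   state error rate and the median absolute deviation of sAGP (over
#'   correct-state segments and over all non-missing segments).
#' @export
evaluateSagp <- function(segments) {
  mc <- mcols(segments)
  strata <- c(unique(mc$clone), "all")
  do.call(rbind, lapply(strata, function(st) {
    sel <- if (st == "all") rep(TRUE, length(segments)) else mc$clone == st
    nb <- mc$nB[sel]; nt <- mc$nT[sel]; p <- mc$sAGP[sel]
    tnb <- mc$trueNb[sel]; tnt <- mc$trueNt[sel]; tp <- mc$trueP[sel]
    stateOk <- !is.na(nb) & nb == tnb & nt == tnt
    errRate <- mean(!stateOk)
    dev <- abs(p - tp)
    data.frame(stratum = st, n = sum(sel), stateErrorRate = errRate,
               madCorrectState = if (any(stateOk))
                 median(dev[stateOk]) else NA_real_,
               madAll = if (any(!is.na(dev)))
                 median(dev, na.rm = TRUE) else NA_real_,
               missingRate = mean(is.na(p)))
  }))
}

#' Score CCF estimates against simulation truth
#'
#' @param variants GRanges from [estimateCCF()] run on [simulateVariants()]
#'   output (truth columns present).
#' @param by optional stratification column ("hostClone", "hostType",
#'   "trueScenario"); NULL for overall only.
#' @return data.frame with Spearman rho, Pearson r, MAD and counts per
#'   stratum (strata with fewer than 3 scored pairs report NA).
#' @export
evaluateCcf <- function(variants, by = NULL) {
  mc <- mcols(variants)
  score <- function(sel) {
    ok <- sel & !is.na(mc$ccf) & !is.na(mc$trueCcf)
    if (sum(ok) < 3L)
      return(data.frame(n = sum(sel), nScored = sum(ok),
                        spearman = NA_real_, pearson = NA_real_,
                        mad = NA_real_))
    data.frame(n = sum(sel), nScored = sum(ok),
               spearman = cor(mc$trueCcf[ok], mc$ccf[ok],
                              method = "spearman"),
               pearson = cor(mc$trueCcf[ok], mc$ccf[ok]),
               mad = median(abs(mc$trueCcf[ok] - mc$ccf[ok])))
  }
  if (is.null(by)) {
    cbind(stratum = "all", score(rep(TRUE, length(variants))))
  } else {
    lv <- unique(mc[[by]])
    lv <- lv[!is.na(lv)]
    out <- do.call(rbind, lapply(lv, function(v)
      cbind(stratum = v, score(!is.na(mc[[by]]) & mc[[by]] == v))))
    rbind(out, cbind(stratum = "all", score(rep(TRUE, length(variants)))))
  }
}

#' Run the CCF validation protocol
#'
#' For each (pDom, pSub) case and coverage: simulate 200+200 segments, fit
#' sAGP, simulate `nSnv` scenario-constrained variants on the fitted
#' segments, estimate CCF, and report the true-vs-estimated correlation.
#'
#' @param cases data.frame with columns `pDom`, `pSub` (default: the four
#'   benchmark cases (0.9,0.8), (0.9,0.4), (0.5,0.3), (0.3,0.1)).
#' @param coverages mean depths to test (default c(50, 100)).
#' @param nSnv variants per case (default 4000).
#' @param seed integer seed; each case uses a distinct derived stream.
#' @return data.frame with one row per case x coverage: Spearman, Pearson,
#'   MAD and the non-missing fraction.
#' @export
runCcfValidation <- function(cases = data.frame(
                               pDom = c(0.9, 0.9, 0.5, 0.3),
                               pSub = c(0.8, 0.4, 0.3, 0.1)),
                             coverages = c(50, 100), nSnv = 4000L,
                             seed = 1L) {
  out <- list()
  k <- 0L
  for (i in seq_len(nrow(cases))) {
    segSeed <- (seed * 131L + i) %% .Machine$integer.max
    segs <- simulateSegments(cases$pDom[i], cases$pSub[i], seed = segSeed)
    segs <- estimateSAGP(segs)
    for (cov in coverages) {
      k <- k + 1L
      vSeed <- (segSeed * 17L + round(cov)) %% .Machine$integer.max
      v <- simulateVariants(segs, nSnv = nSnv, coverage = cov, seed = vSeed)
      v <- estimateCCF(v, segs, minDepth = 0L, minSaf = 0)
      sc <- evaluateCcf(v)
      out[[k]] <- data.frame(pDom = cases$pDom[i], pSub = cases$pSub[i],
                             coverage = cov, spearman = sc$spearman,
                             pearson = sc$pearson, mad = sc$mad,
                             fracScored = sc$nScored / sc$n)
    }
  }
  do.call(rbind, out)
}

#' Run the three-method comparison protocol (this package's side)
#'
#' Simulates 200 CNA regions with sAGP drawn from U(0,1) (states at the 2/7,
#' 2/7, 2/7, 1/7 ratios) plus euploid intervals making up half the genome by
#' length, places `nMut` mutations uniformly, runs the full sAGP + CCF
#' pipeline at mean coverage `coverage`, and scores in-sCNA mutations. Two
#' deliberately mis-specified ablation estimators are scored alongside: one
#' that ignores the mutation-only population (always applies the B/C
#' expression) and one that always applies the A1 expression.
#'
#' @param seed integer seed.
#' @param nCna,nMut,coverage protocol sizes (defaults 200, 1000, 50).
#' @return list with `variants`, `metrics` (overall Pearson/Spearman/MAD for
#'   in-sCNA mutations), `byStratum` (sCNA-type x scenario table), and
#'   `ablation` (Pearson r of the two mis-specified estimators).
#' @export
runComparisonProtocol <- function(seed = 1L, nCna = 200L, nMut = 1000L,
                                  coverage = 50) {
  segs <- simulateSegments(nEuploid = nCna, nScna = nCna, pRandom = TRUE,
                           seed = seed)
  segs <- estimateSAGP(segs)
  v <- simulateVariants(segs, nSnv = nMut, coverage = coverage,
                        seed = (seed * 31L + 7L) %% .Machine$integer.max)
  v <- estimateCCF(v, segs, minDepth = 0L, minSaf = 0)
  mc <- mcols(v)
  inScna <- mc$trueScenario != "euploid"
  metrics <- evaluateCcf(v[inScna])
  byStr <- do.call(rbind, lapply(
    split(seq_len(sum(inScna)), paste(mc$hostType[inScna],
                                      mc$trueScenario[inScna], sep = ":")),
    function(ii) {
      vv <- v[inScna][ii]
      cbind(stratum = paste(mcols(vv)$hostType[1L],
                            mcols(vv)$trueScenario[1L], sep = ":"),
            evaluateCcf(vv)[, -1L])
    }))
  # ablations: expression forced regardless of the inferred scenario
  ab <- function(expr) {
    est <- vapply(which(inScna), function(i) {
      nb <- mc$nB[i]; nt <- mc$nT[i]; p <- mc$sAGP[i]
      if (is.na(p) || p <= 0) return(NA_real_)
      min(max(ccfExpression(mc$saf[i], nb, nt, p, expr), 0), 1)
    }, 1)
    ok <- !is.na(est)
    cor(mc$trueCcf[inScna][ok], est[ok])
  }
  list(variants = v, metrics = metrics, byStratum = byStr,
       ablation = c(ignoreR1 = ab("B"), forceA1 = ab("A1")),
       nInScna = sum(inScna))
}
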