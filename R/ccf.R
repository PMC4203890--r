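# CCF inference: scenario taxonomy, admissible SAF zones, posterior scenario
# probabilities and CCF point estimates with posterior moments.

.SCENARIOS <- c("A1", "A2", "B", "C")

#' Admissible mutation/sCNA order-phase scenarios for a copy state
#'
#' Scenario A1/A2: the mutation preceded the sCNA, occurring on the parental
#' chromosome that was subsequently amplified/retained (A1) versus the other
#' one (A2). B: the sCNA preceded the mutation. C: mutation and sCNA arose in
#' independent lineages. For copy-neutral LOH and balanced gains
#' (`nB = nT/2 > 1`) scenario A2 is degenerate (it collapses onto C) and the
#' admissible set is `{A1, B, C}`; hemizygous states keep all four.
#'
#' @param nB,nT minor/total copy number of a non-euploid sCNA state.
#' @return Character vector of scenario labels.
#' @export
admissibleScenarios <- function(nB, nT) {
  if (nB == 1L && nT == 2L)
    stop("euploid state has no mutation/sCNA scenarios")
  if (nB == 0L && nT >= 2L) return(c("A1", "B", "C"))       # LOH
  if (nB >= 1L && nT == 2L * nB) return(c("A1", "B", "C"))  # balanced gain
  .SCENARIOS
}

# CCF = nbar*f + offset; the offset fully characterizes the expression
.ccfOffset <- function(nB, nT, p, scenario) {
  nA <- nT - nB
  switch(scenario,
         A1 = -p * (nA - 1),
         A2 = if (nB >= 1L) -p * (nB - 1) else 0,
         B = 0, C = 0,
         stop("unknown scenario: ", scenario))
}

#' Scenario-specific CCF expression
#'
#' With `nbar = 2(1-p) + nT*p` the mean local copy number, the cancer cell
#' fraction implied by a somatic allele frequency `f` is
#' `nbar*f - p*(nA - 1)` under A1, `nbar*f - p*(nB - 1)` under A2 (for
#' `nB >= 1`), and `nbar*f` under B and C. For `nB = 0` states A2 shares the
#' B/C expression: CCF counts cells physically carrying at least one mutant
#' copy, and cells that lost the mutant allele do not count.
#'
#' @param f somatic allele frequency (vectorized).
#' @param nB,nT copy state.
#' @param p sAGP of the host sCNA, in (0, 1].
#' @param scenario one of "A1", "A2", "B", "C".
#' @return CCF value(s), unclipped.
#' @export
ccfExpression <- function(f, nB, nT, p, scenario) {
  meanCopyNumber(p, nT) * f + .ccfOffset(nB, nT, p, scenario)
}

#' Admissible SAF interval of a scenario
#'
#' The range of somatic allele frequencies attainable under a scenario, given
#' the host state and its sAGP, obtained from the three-subpopulation model
#' (`r0` ancestral, `r1`/`r2` as in the scenario diagrams):
#' A1 `[nA*p, 1-p+nA*p]/nbar`; A2 `[nB*p, 1-p+nB*p]/nbar` for `nB >= 1` and
#' `[0, 1-p]/nbar` (the C zone) for `nB = 0`; B `[0, p]/nbar`;
#' C `[0, 1-p]/nbar`.
#'
#' @inheritParams ccfExpression
#' @return numeric `c(fl, fh)`.
#' @export
safBounds <- function(nB, nT, p, scenario) {
  nA <- nT - nB
  nbar <- meanCopyNumber(p, nT)
  b <- switch(scenario,
              A1 = c(nA * p, 1 - p + nA * p),
              A2 = if (nB >= 1L) c(nB * p, 1 - p + nB * p) else c(0, 1 - p),
              B = c(0, p),
              C = c(0, 1 - p),
              stop("unknown scenario: ", scenario))
  b / nbar
}

#' Posterior scenario probabilities from somatic read counts
#'
#' The likelihood of scenario X is the binomial probability of the observed
#' somatic read count integrated over the scenario's admissible SAF interval
#' (flat prior on the true SAF), evaluated in closed form through the
#' regularized incomplete beta function:
#' \deqn{p_X = \int_{f_l^X}^{f_h^X} \binom{N}{S} f^S (1-f)^{N-S} df
#'   = [I_{f_h}(S+1, N-S+1) - I_{f_l}(S+1, N-S+1)]/(N+1).}
#' Probabilities are normalized over the admissible scenarios. If every
#' integral underflows to zero (observed SAF far outside all zones) a uniform
#' distribution is returned with `outOfZone = TRUE`.
#'
#' @param S somatic-allele read count.
#' @param N total read depth (>= 1).
#' @param nB,nT copy state.
#' @param p sAGP in (0, 1).
#' @return list with named numeric `probs` and logical `outOfZone`.
#' @export
scenarioProbabilities <- function(S, N, nB, nT, p) {
  stopifnot(N >= 1, S >= 0, S <= N)
  sc <- admissibleScenarios(nB, nT)
  pX <- vapply(sc, function(x) {
    b <- safBounds(nB, nT, p, x)
    (pbeta(b[2L], S + 1, N - S + 1) - pbeta(b[1L], S + 1, N - S + 1)) /
      (N + 1)
  }, 1)
  tot <- sum(pX)
  if (tot <= 0 || !is.finite(tot))
    return(list(probs = setNames(rep(1 / length(sc), length(sc)), sc),
                outOfZone = TRUE))
  list(probs = pX / tot, outOfZone = FALSE)
}

#' Smallest scenario combination reaching a probability threshold
#'
#' Searches single scenarios, then pairs, then triples, then the full
#' admissible set, within each size class in order of decreasing summed
#' probability (exact ties: lexicographic scenario order), and returns the
#' first combination whose summed probability reaches `threshold`. The full
#' set is the terminal fallback.
#'
#' @param probs named normalized probabilities over admissible scenarios.
#' @param threshold assignment threshold (default 0.95).
#' @return character vector of scenario labels.
#' @export
assignScenario <- function(probs, threshold = 0.95) {
  sc <- names(probs)
  for (k in seq_len(length(sc) - 1L)) {
    combos <- utils::combn(sc, k, simplify = FALSE)
    sums <- vapply(combos, function(cc) sum(probs[cc]), 1)
    for (i in order(-sums)) {
      if (sums[i] >= threshold) return(combos[[i]])
    }
  }
  sc
}

#' CCF point estimate for an assigned scenario set
#'
#' If every scenario in the set shares one CCF expression for the state, it
#' is evaluated at the observed SAF (clipped to [0,1]; the pre-clip value is
#' retained for QC). If the expressions differ (a set joining A1 with another
#' scenario, for amplification or CN-LOH), the CCF is missing and the
#' distinct candidate values are reported.
#'
#' @param f observed somatic allele frequency.
#' @param nB,nT copy state.
#' @param p sAGP in (0, 1).
#' @param assignedSet character vector from [assignScenario()].
#' @return list with `ccf` (clipped or NA), `ccfPreclip`, and `candidates`
#'   (distinct unclipped values, one per expression group).
#' @export
ccfPointEstimate <- function(f, nB, nT, p, assignedSet) {
  offs <- vapply(assignedSet, .ccfOffset, 1, nB = nB, nT = nT, p = p)
  vals <- meanCopyNumber(p, nT) * f + offs
  uniq <- unique(round(vals, 12L))
  if (length(uniq) == 1L)
    list(ccf = min(max(uniq, 0), 1), ccfPreclip = uniq, candidates = uniq)
  else
    list(ccf = NA_real_, ccfPreclip = NA_real_, candidates = sort(uniq))
}

#' Posterior mean and variance of CCF
#'
#' Models the somatic read count as Binomial(N, G(x)) where G(x) is the SAF
#' implied by CCF = x under the scenario (the inverse of the CCF expression,
#' clipped to [0,1]). With a flat prior on x in [0,1], the posterior moments
#' are ratios of integrals evaluated by Simpson's rule on a fixed grid.
#'
#' @param S,N somatic and total read counts.
#' @param nB,nT copy state (use (1,2) with `p = 0` for euploid loci).
#' @param p sAGP in [0, 1].
#' @param scenario representative scenario of the shared-expression set.
#' @param nGrid odd number of quadrature points (default 2001).
#' @return list with `ccfExp`, `ccfVar`, and `degenerate` (TRUE when the
#'   normalizing integral vanishes).
#' @export
ccfPosteriorMoments <- function(S, N, nB, nT, p, scenario = "B",
                                nGrid = 2001L) {
  stopifnot(nGrid %% 2L == 1L, nGrid >= 5L)
  nbar <- meanCopyNumber(p, nT)
  off <- .ccfOffset(nB, nT, p, scenario)
  x <- seq(0, 1, length.out = nGrid)
  G <- pmin(pmax((x - off) / nbar, 0), 1)
  dens <- dbinom(S, N, G)
  w <- c(1, rep(c(4, 2), length.out = nGrid - 2L), 1)
  h <- x[2L] - x[1L]
  I0 <- sum(w * dens) * h / 3
  if (!is.finite(I0) || I0 <= 0)
    return(list(ccfExp = NA_real_, ccfVar = NA_real_, degenerate = TRUE))
  I1 <- sum(w * dens * x) * h / 3
  I2 <- sum(w * dens * x^2) * h / 3
  e <- I1 / I0
  list(ccfExp = e, ccfVar = max(I2 / I0 - e^2, 0), degenerate = FALSE)
}

#' Estimate CCF for every somatic variant
#'
#' Looks up each variant's host segment. Variants in euploid territory (no
#' overlapping sCNA, or sAGP 0) use the diploid relation CCF = 2*SAF.
#' Variants inside an sCNA whose sAGP could not be estimated get a missing
#' CCF. Otherwise the scenario machinery runs: posterior scenario
#' probabilities, smallest assigned set at `threshold`, shared-expression
#' point estimate, and posterior moments. Out-of-zone observations fall back
#' to the B/C expression and are flagged.
#'
#' @param variants GRanges from [readSomaticVariants()].
#' @param segments GRanges from [estimateSAGP()] (columns `nB`, `nT`,
#'   `sAGP`), or NULL to treat every variant as euploid.
#' @param threshold scenario-assignment threshold (default 0.95).
#' @param minDepth,minSaf QC filters; variants failing them are flagged
#'   "filtered" with missing CCF (defaults 20 and 0.05; set to 0 to disable).
#' @param nGrid quadrature points for posterior moments.
#' @return The variants GRanges with columns `nB`, `nT`, `sAGP`,
#'   `scenarioSet`, `pA1`, `pA2`, `pB`, `pC`, `ccf`, `ccfPreclip`, `ccfExp`,
#'   `ccfVar`, `flag` added.
#' @export
estimateCCF <- function(variants, segments = NULL, threshold = 0.95,
                        minDepth = 20L, minSaf = 0.05, nGrid = 2001L) {
  n <- length(variants)
  res <- data.frame(nB = rep(NA_integer_, n), nT = NA_integer_,
                    sAGP = NA_real_, scenarioSet = NA_character_,
                    pA1 = NA_real_, pA2 = NA_real_, pB = NA_real_,
                    pC = NA_real_, ccf = NA_real_, ccfPreclip = NA_real_,
                    ccfExp = NA_real_, ccfVar = NA_real_,
                    flag = "", stringsAsFactors = FALSE)
  segIdx <- rep(NA_integer_, n)
  if (!is.null(segments) && length(segments)) {
    ov <- findOverlaps(variants, segments, select = "first")
    segIdx <- as.integer(ov)
  }
  for (i in seq_len(n)) {
    S <- mcols(variants)$S[i]; N <- mcols(variants)$N[i]
    f <- S / N
    if (N < minDepth || f < minSaf) {
      res$flag[i] <- "filtered"
      next
    }
    j <- segIdx[i]
    hostP <- if (!is.na(j)) mcols(segments)$sAGP[j] else 0
    hostNb <- if (!is.na(j)) mcols(segments)$nB[j] else 1L
    hostNt <- if (!is.na(j)) mcols(segments)$nT[j] else 2L
    if (!is.na(j) && is.na(hostP)) {
      # sCNA failed the regional mixing model: CCF not estimable
      res$flag[i] <- "host_sagp_missing"
      next
    }
    euploid <- is.na(j) || hostP <= 0 ||
      (hostNb == 1L && hostNt == 2L)
    if (euploid) {
      res$sAGP[i] <- 0; res$nB[i] <- 1L; res$nT[i] <- 2L
      res$ccfPreclip[i] <- 2 * f
      res$ccf[i] <- min(2 * f, 1)
      mom <- ccfPosteriorMoments(S, N, 1L, 2L, 0, "B", nGrid)
      res$ccfExp[i] <- mom$ccfExp; res$ccfVar[i] <- mom$ccfVar
      res$flag[i] <- "euploid"
      next
    }
    res$sAGP[i] <- hostP; res$nB[i] <- hostNb; res$nT[i] <- hostNt
    sp <- scenarioProbabilities(S, N, hostNb, hostNt, hostP)
    pr <- sp$probs
    for (sc in names(pr))
      res[[paste0("p", sc)]][i] <- pr[[sc]]
    if (sp$outOfZone) {
      res$scenarioSet[i] <- paste(names(pr), collapse = "/")
      v <- ccfExpression(f, hostNb, hostNt, hostP, "B")
      res$ccfPreclip[i] <- v
      res$ccf[i] <- min(max(v, 0), 1)
      mom <- ccfPosteriorMoments(S, N, hostNb, hostNt, hostP, "B", nGrid)
      res$ccfExp[i] <- mom$ccfExp; res$ccfVar[i] <- mom$ccfVar
      res$flag[i] <- "out_of_zone"
      next
    }
    aset <- assignScenario(pr, threshold)
    res$scenarioSet[i] <- paste(aset, collapse = "/")
    pe <- ccfPointEstimate(f, hostNb, hostNt, hostP, aset)
    res$ccf[i] <- pe$ccf
    res$ccfPreclip[i] <- pe$ccfPreclip
    if (is.na(pe$ccf)) {
      res$flag[i] <- paste0("conflicting:",
                            paste(signif(pe$candidates, 6),
                                  collapse = ","))
      next
    }
    mom <- ccfPosteriorMoments(S, N, hostNb, hostNt, hostP, aset[1L], nGrid)
    res$ccfExp[i] <- mom$ccfExp; res$ccfVar[i] <- mom$ccfVar
  }
  mcols(variants) <- cbind(mcols(variants), DataFrame(res))
  variants
}
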