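test_that("admissible scenario sets follow the state taxonomy", {
  expect_equal(admissibleScenarios(1L, 3L), c("A1", "A2", "B", "C"))
  expect_equal(admissibleScenarios(0L, 1L), c("A1", "A2", "B", "C"))
  expect_equal(admissibleScenarios(0L, 2L), c("A1", "B", "C"))
  expect_equal(admissibleScenarios(2L, 4L), c("A1", "B", "C"))
  expect_error(admissibleScenarios(1L, 2L), "euploid")
})

test_that("CCF expressions reproduce the per-type formulas", {
  # amplification A1: f(2+p) - p
  expect_equal(ccfExpression(0.4, 1L, 3L, 0.5, "A1"), 0.4 * 2.5 - 0.5)
  expect_equal(ccfExpression(0.4, 1L, 3L, 0.5, "A2"), 0.4 * 2.5)
  expect_equal(ccfExpression(0.4, 1L, 3L, 0.5, "B"), 0.4 * 2.5)
  # CN-LOH: A1 2f - p, others 2f
  expect_equal(ccfExpression(0.6, 0L, 2L, 0.3, "A1"), 2 * 0.6 - 0.3)
  expect_equal(ccfExpression(0.6, 0L, 2L, 0.3, "B"), 1.2)
  # deletion: every scenario f(2 - p)
  for (sc in c("A1", "A2", "B", "C"))
    expect_equal(ccfExpression(0.5, 0L, 1L, 0.6, sc),
                 if (sc == "A1") 0.5 * 1.4 - 0.6 * 0 + 0 else 0.5 * 1.4)
  expect_equal(ccfExpression(0.5, 0L, 1L, 0.6, "A1"), 0.5 * (2 - 0.6))
  # at the A1 upper SAF bound, CCF = 1 for any p (algebraic identity)
  for (p in seq(0.1, 0.9, by = 0.1)) {
    expect_equal(ccfExpression((1 + p) / (2 + p), 1L, 3L, p, "A1"), 1,
                 tolerance = 1e-12)
    expect_equal(ccfExpression(1 / (2 - p), 0L, 1L, p, "A1"), 1,
                 tolerance = 1e-12)
  }
})

test_that("SAF bounds match the per-type formulas", {
  expect_equal(safBounds(1L, 3L, 0.5, "A1"), c(0.4, 0.6))
  expect_equal(safBounds(1L, 3L, 0.5, "A2"), c(0.2, 0.4))
  expect_equal(safBounds(1L, 3L, 0.5, "B"), c(0, 0.2))
  expect_equal(safBounds(1L, 3L, 0.5, "C"), c(0, 0.2))
  expect_equal(safBounds(0L, 2L, 0.4, "A1"), c(0.4, 0.7))
  expect_equal(safBounds(0L, 2L, 0.4, "C"), c(0, 0.3))
  p <- 0.6
  expect_equal(safBounds(0L, 1L, p, "A1"), c(p, 1) / (2 - p))
  expect_equal(safBounds(0L, 1L, p, "B"), c(0, p / (2 - p)))
})

test_that("bounds agree with brute-force subpopulation enumeration", {
  states <- list(c(1L, 3L), c(0L, 2L), c(0L, 1L), c(2L, 4L))
  for (st in states) {
    for (p in seq(0.1, 0.9, by = 0.1)) {
      for (sc in admissibleScenarios(st[1], st[2])) {
        oracle <- oracleSafRange(st[1], st[2], p, sc)
        expect_equal(safBounds(st[1], st[2], p, sc), oracle,
                     tolerance = 1e-9,
                     info = sprintf("state (%d,%d) p=%.1f %s",
                                    st[1], st[2], p, sc))
      }
    }
  }
})

test_that("per-type expressions agree with the general form for nB >= 1", {
  fGrid <- seq(0.05, 0.6, by = 0.05)
  for (p in seq(0.1, 0.9, by = 0.2)) {
    nbar <- meanCopyNumber(p, 3L)
    expect_equal(ccfExpression(fGrid, 1L, 3L, p, "A1"),
                 nbar * fGrid - p * 2 + p)
    expect_equal(ccfExpression(fGrid, 1L, 3L, p, "A2"),
                 nbar * fGrid - p * 1 + p)
    expect_equal(ccfExpression(fGrid, 1L, 3L, p, "C"), nbar * fGrid)
  }
})

test_that("CCF stays in [0,1] inside every admissible zone", {
  for (st in list(c(1L, 3L), c(0L, 2L), c(0L, 1L), c(2L, 4L))) {
    for (p in seq(0.1, 0.9, by = 0.1)) {
      for (sc in admissibleScenarios(st[1], st[2])) {
        b <- safBounds(st[1], st[2], p, sc)
        f <- seq(b[1], b[2], length.out = 21)
        ccf <- ccfExpression(f, st[1], st[2], p, sc)
        expect_true(all(ccf >= -1e-9 & ccf <= 1 + 1e-9),
                    info = sprintf("(%d,%d) p=%.1f %s", st[1], st[2], p, sc))
      }
    }
  }
})

test_that("closed-form scenario probabilities match adaptive quadrature", {
  cases <- expand.grid(S = c(5L, 10L, 50L, 250L), Nmult = c(2L, 4L),
                       p = c(0.3, 0.5, 0.8))
  for (i in seq_len(nrow(cases))) {
    S <- cases$S[i]; N <- S * cases$Nmult[i]; p <- cases$p[i]
    for (st in list(c(1L, 3L), c(0L, 2L), c(0L, 1L))) {
      sc <- admissibleScenarios(st[1], st[2])
      raw <- vapply(sc, function(x) {
        b <- safBounds(st[1], st[2], p, x)
        oracleScenarioProb(S, N, b[1], b[2])
      }, 1)
      got <- scenarioProbabilities(S, N, st[1], st[2], p)
      expect_false(got$outOfZone)
      expect_equal(unname(got$probs), unname(raw / sum(raw)),
                   tolerance = 1e-8)
    }
  }
})

test_that("scenario probabilities concentrate where the SAF indicates", {
  # f = 0.5 with p = 0.5 lies only in the amplification A1 zone
  pr <- scenarioProbabilities(50L, 100L, 1L, 3L, 0.5)$probs
  expect_gt(pr[["A1"]], 0.97)
  # f = 0.1 lies in the (equal-width) B and C zones, below A2's lower bound
  pr <- scenarioProbabilities(10L, 100L, 1L, 3L, 0.5)$probs
  expect_equal(unname(pr[["B"]]), unname(pr[["C"]]), tolerance = 1e-12)
  expect_gt(pr[["B"]], 0.45)
  expect_lt(pr[["A1"]] + pr[["A2"]], 0.02)
  # deletion, all reads somatic at high p: mass concentrated on A1
  # (quadrature: f^20 integrated over the A1 zone [0.818, 0.909] dominates)
  pr <- scenarioProbabilities(20L, 20L, 0L, 1L, 0.9)$probs
  expect_equal(names(which.max(pr)), "A1")
  expect_gt(pr[["A1"]], 0.85)
})

test_that("scenario assignment searches singles, pairs, triples, full set", {
  pr <- c(A1 = 0.97, A2 = 0.01, B = 0.01, C = 0.01)
  expect_equal(assignScenario(pr), "A1")
  pr <- c(A1 = 0.50, A2 = 0.02, B = 0.24, C = 0.24)
  expect_equal(sort(assignScenario(pr)), c("A1", "B", "C"))
  pr <- c(A1 = 0.25, A2 = 0.25, B = 0.25, C = 0.25)
  expect_equal(assignScenario(pr), c("A1", "A2", "B", "C"))
  pr <- c(A1 = 0.6, A2 = 0.37, B = 0.02, C = 0.01)
  expect_equal(sort(assignScenario(pr)), c("A1", "A2"))
  # the search space over four scenarios has 2^4 - 1 = 15 combinations
  nCombos <- sum(choose(4, 1:4))
  expect_equal(nCombos, 15)
})

test_that("point estimates require a shared expression", {
  # {B, C} share the amplification expression
  pe <- ccfPointEstimate(0.2, 1L, 3L, 0.5, c("B", "C"))
  expect_equal(pe$ccf, 0.5)
  # {A1, C} conflict for amplification: both candidates retained
  pe <- ccfPointEstimate(0.3, 1L, 3L, 0.5, c("A1", "C"))
  expect_true(is.na(pe$ccf))
  expect_equal(sort(pe$candidates), sort(c(0.3 * 2.5 - 0.5, 0.3 * 2.5)))
  # deletion is always estimable
  pe <- ccfPointEstimate(0.5, 0L, 1L, 0.6, c("A1", "A2", "B", "C"))
  expect_equal(pe$ccf, 0.5 * 1.4)
  # clipping retains the pre-clip value
  pe <- ccfPointEstimate(0.9, 0L, 1L, 0.1, "A1")
  expect_equal(pe$ccf, 1)
  expect_gt(pe$ccfPreclip, 1)
})

test_that("posterior moments are consistent and shrink with depth", {
  m <- ccfPosteriorMoments(250L, 1000L, 1L, 2L, 0, "B")
  expect_lt(abs(m$ccfExp - 0.5), 0.01)
  mLo <- ccfPosteriorMoments(25L, 100L, 1L, 2L, 0, "B")
  expect_gt(mLo$ccfVar, m$ccfVar)
  # expectation converges to the point expression at high depth
  for (st in list(c(1L, 3L), c(0L, 1L))) {
    p <- 0.5
    f <- mean(safBounds(st[1], st[2], p, "A1"))
    N <- 10000L; S <- round(f * N)
    m <- ccfPosteriorMoments(S, N, st[1], st[2], p, "A1")
    expect_lt(abs(m$ccfExp - ccfExpression(S / N, st[1], st[2], p, "A1")),
              5e-3)
  }
  # degenerate: impossible counts under every CCF
  m <- ccfPosteriorMoments(100L, 100L, 1L, 3L, 0.1, "B")
  expect_true(m$degenerate || m$ccfExp > 0.9)
})

test_that("variant-level estimation routes euploid, missing and sCNA hosts", {
  segs <- GRanges("chr1", IRanges(c(1, 1001, 2001), width = 1000),
                  nB = c(1L, 0L, NA), nT = c(2L, 2L, NA),
                  sAGP = c(0, 0.6, NA))
  v <- GRanges("chr1", IRanges(c(500, 1500, 2500, 5000), width = 1),
               S = c(25L, 60L, 30L, 10L), N = c(100L, 100L, 100L, 100L),
               saf = c(0.25, 0.6, 0.3, 0.1))
  out <- estimateCCF(v, segs, minDepth = 0L, minSaf = 0)
  mc <- mcols(out)
  expect_equal(mc$ccf[1], 0.5)              # euploid region: 2f
  expect_equal(mc$flag[1], "euploid")
  # CN-LOH host, f = 0.6 > (1+p)/2 boundary region: A1 zone
  expect_equal(mc$scenarioSet[2], "A1")
  expect_equal(mc$ccf[2], 2 * 0.6 - 0.6)
  expect_equal(mc$flag[3], "host_sagp_missing")  # NA propagation
  expect_true(is.na(mc$ccf[3]))
  expect_equal(mc$ccf[4], 0.2)              # off-segment variant: diploid
})

test_that("QC filters flag shallow or low-SAF variants", {
  v <- GRanges("chr1", IRanges(c(100, 200), width = 1),
               S = c(2L, 30L), N = c(100L, 10L), saf = c(0.02, 3))
  mcols(v)$saf <- mcols(v)$S / mcols(v)$N
  out <- estimateCCF(v, NULL)
  expect_equal(mcols(out)$flag, c("filtered", "filtered"))
})
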