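test_that("canonical positions match the mixing-model geometry", {
  # pure euploid is the origin for any state
  for (st in list(c(0, 1), c(0, 2), c(1, 3), c(2, 4))) {
    pos <- canonicalPosition(st[1], st[2], 0)
    expect_equal(c(pos$baf, pos$lrr), c(0, 0))
  }
  # full CN-LOH: folded BAF 0.5, copy-neutral LRR 0
  pos <- canonicalPosition(0, 2, 1)
  expect_equal(c(pos$baf, pos$lrr), c(0.5, 0))
  # direct evaluation, independently: (1,3) at p=0.6 has nbar=2.6,
  # baf = |1.0/2.6 - 0.5| = 0.1153846, lrr = log2(2.6) - 1
  pos <- canonicalPosition(1, 3, 0.6)
  expect_equal(pos$baf, abs(1.0 / 2.6 - 0.5), tolerance = 1e-9)
  expect_equal(pos$lrr, log2(2.6) - 1, tolerance = 1e-9)
  # baseline shifts translate the whole line
  bl <- SampleBaseline(x0 = 0.02, y0 = 0.3)
  pos2 <- canonicalPosition(1, 3, 0.6, bl)
  expect_equal(pos2$baf, pos$baf + 0.02)
  expect_equal(pos2$lrr, pos$lrr + 0.3)
  expect_error(canonicalPosition(0, 0, 1), "degenerate")
})

test_that("distance to origin is non-decreasing in p along every line", {
  ps <- seq(0, 1, by = 0.01)
  st <- candidateStates()
  for (j in seq_len(nrow(st))) {
    pos <- canonicalPosition(st$nB[j], st$nT[j], ps)
    d <- sqrt(pos$baf^2 + pos$lrr^2)
    expect_true(all(diff(d) > -1e-9),
                info = paste("state", st$nB[j], st$nT[j]))
  }
})

test_that("candidate state enumeration excludes euploid and minor > major", {
  st <- candidateStates(6L)
  expect_false(any(st$nB == 1L & st$nT == 2L))
  expect_true(all(st$nB <= st$nT - st$nB))
  expect_true(all(st$nT <= 6L))
  expect_true(all(c("0 1", "0 2", "1 3", "2 4") %in%
                    paste(st$nB, st$nT)))
})

test_that("noiseless canonical positions invert to their state and p", {
  bl <- SampleBaseline(sdBaf = 1e-3, sdLrr = 1e-3, pS = 0.5, ploidy = 2)
  st <- candidateStates()
  thr <- baselineThreshold(bl)
  for (j in seq_len(nrow(st))) {
    for (p in seq(0.05, 0.95, by = 0.1)) {
      pos <- canonicalPosition(st$nB[j], st$nT[j], p, bl)
      # skip points shared with another line (within the noise threshold)
      lineDist <- function(k) {
        pg <- canonicalPosition(st$nB[k], st$nT[k],
                                seq(0, 1, length.out = 501), bl)
        min(sqrt((pg$baf - pos$baf)^2 + (pg$lrr - pos$lrr)^2))
      }
      dOther <- vapply(setdiff(seq_len(nrow(st)), j), lineDist, 1)
      if (any(dOther < thr) || sqrt(pos$baf^2 + pos$lrr^2) <= thr) next
      fit <- fitSAGP(pos$baf, pos$lrr, bl)
      expect_equal(fit$nB, st$nB[j])
      expect_equal(fit$nT, st$nT[j])
      expect_equal(fit$p, p, tolerance = 1e-3)
    }
  }
})

test_that("euploid calls, missing calls and mean copy number behave", {
  bl <- SampleBaseline(sdBaf = 0.01, sdLrr = 0.04, pS = 0.5, ploidy = 2)
  fit <- fitSAGP(0, 0, bl)
  expect_equal(fit$p, 0)
  expect_equal(c(fit$nB, fit$nT), c(1L, 2L))
  # far outside every canonical line
  fit <- fitSAGP(0.45, -2.5, bl)
  expect_true(is.na(fit$p) && is.na(fit$nB))
  expect_equal(fit$nCandidates, 0L)
  expect_equal(meanCopyNumber(0, 5L), 2)
  expect_equal(meanCopyNumber(1, 3L), 3)
  expect_equal(meanCopyNumber(0.5, 3L), 2.5)
})

test_that("baseline estimation finds the balanced cluster and is shift-invariant", {
  set.seed(5)
  segs <- simulateSegments(0.8, 0.3, seed = 5)
  bl <- estimateBaseline(segs)
  expect_lt(abs(bl@x0), 0.01)
  expect_lt(abs(bl@y0), 0.02)
  expect_lt(abs(bl@sdBaf - 0.01), 0.005)
  expect_lt(abs(bl@sdLrr - 0.04), 0.02)

  shifted <- segs
  mcols(shifted)$medLrr <- mcols(shifted)$medLrr + 0.3
  bl2 <- estimateBaseline(shifted)
  expect_equal(bl2@y0, bl@y0 + 0.3, tolerance = 0.02)
  f1 <- estimateSAGP(segs)
  f2 <- estimateSAGP(shifted)
  expect_equal(mcols(f2)$sAGP, mcols(f1)$sAGP, tolerance = 0.02)

  # all segments strongly unbalanced -> no baseline
  bad <- segs
  mcols(bad)$medFbaf <- 0.4
  expect_error(estimateBaseline(bad), "unanalyzable|balanced")
})

test_that("global context: ploidy is length-weighted, pS is the sAGP mode", {
  gr <- GRanges("chr1", IRanges(c(1, 101), width = c(100, 100)),
                nT = c(2L, 3L), sAGP = c(0, 1))
  ctx <- estimateGlobalContext(gr)
  expect_equal(ctx$ploidy, 2.5)
  gr2 <- GRanges("chr1", IRanges(seq(1, 2000, by = 100)[1:20], width = 50),
                 nT = rep(3L, 20),
                 sAGP = c(rep(0.9, 15), rep(0.3, 5)))
  expect_equal(estimateGlobalContext(gr2)$pS, 0.9, tolerance = 0.05)
  # all-euploid genome
  gr3 <- GRanges("chr1", IRanges(1, 100), nT = 2L, sAGP = 0)
  ctx3 <- estimateGlobalContext(gr3)
  expect_equal(ctx3$ploidy, 2)
  expect_equal(ctx3$pS, 0)
})

test_that("two-clone simulations are recovered with few missing segments", {
  segs <- simulateSegments(0.9, 0.6, seed = 17)
  segs <- estimateSAGP(segs)
  ev <- evaluateSagp(segs)
  all <- ev[ev$stratum == "all", ]
  # under the platform noise model, < 5% of true-sCNA segments go missing
  scna <- mcols(segs)$trueP > 0
  expect_lt(mean(is.na(mcols(segs)$sAGP[scna])), 0.05)
  expect_lt(all$stateErrorRate, 0.15)
  dom <- ev[ev$stratum == "dominant", ]
  expect_lt(dom$madCorrectState, 0.05)
  # sample-wide AGP tracks the dominant clone
  bl <- S4Vectors::metadata(segs)$baseline
  expect_equal(bl@pS, 0.9, tolerance = 0.05)
})
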