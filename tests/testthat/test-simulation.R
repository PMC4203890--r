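test_that("segment simulation honors counts, split and the noiseless limit", {
  segs <- simulateSegments(0.9, 0.4, seed = 1)
  expect_equal(length(segs), 400L)
  mc <- mcols(segs)
  expect_equal(sum(mc$clone == "euploid"), 200L)
  expect_equal(sum(mc$clone == "dominant"), 133L)
  expect_equal(sum(mc$clone == "minor"), 67L)
  expect_true(all(mc$trueP[mc$clone == "dominant"] == 0.9))

  s0 <- simulateSegments(0.7, 0.2, sigmaBaf = 0, sigmaLrr = 0, seed = 2)
  mc0 <- mcols(s0)
  i <- which(mc0$trueP > 0)
  pos <- mapply(function(nb, nt, p) {
    cp <- canonicalPosition(nb, nt, p)
    c(cp$baf, cp$lrr)
  }, mc0$trueNb[i], mc0$trueNt[i], mc0$trueP[i])
  expect_equal(mc0$medFbaf[i], pos[1, ], tolerance = 1e-12)
  expect_equal(mc0$medLrr[i], pos[2, ], tolerance = 1e-12)

  # a segment with true p = 0 carries the euploid truth state
  sz <- simulateSegments(0.5, 0, seed = 3)
  mz <- mcols(sz)
  expect_true(all(mz$trueNb[mz$clone == "minor"] == 1L))
  expect_true(all(mz$trueP[mz$clone == "minor"] == 0))
})

test_that("copy states are drawn at the 2:2:2:1 ratios", {
  segs <- simulateSegments(0.9, 0.4, nEuploid = 0L, nScna = 7000L, seed = 4)
  mc <- mcols(segs)
  key <- paste(mc$trueNb, mc$trueNt)
  obs <- table(key)[c("0 1", "0 2", "1 3", "2 4")]
  expected <- 7000 * c(2, 2, 2, 1) / 7
  # multinomial sampling error: ~4 sd
  expect_true(all(abs(obs - expected) < 4 * sqrt(expected)))
})

test_that("the validation grid enumerates the dominant/minor pairs", {
  g <- sagpGrid(0.1)
  expect_equal(nrow(g), 55L)
  expect_equal(sum(g$pDom == 0.1), 1L)
  expect_equal(g$pSub[g$pDom == 0.1], 0)
  g5 <- sagpGrid(0.5)
  expect_equal(nrow(g5), 3L)
  expect_equal(g5, data.frame(pDom = c(0.5, 1, 1), pSub = c(0, 0, 0.5)),
               ignore_attr = TRUE)
  expect_true(all(g$pSub < g$pDom))
})

test_that("simulated variants respect zones, depth and determinism", {
  segs <- estimateSAGP(simulateSegments(0.8, 0.3, seed = 5))
  v <- simulateVariants(segs, nSnv = 2000L, coverage = 50, seed = 6)
  mc <- mcols(v)
  expect_equal(length(v), 2000L)
  expect_equal(mean(mc$N), 50, tolerance = 0.05)
  expect_true(all(mc$N >= 1L))
  # euploid truth: CCF = 2f by construction
  eu <- mc$trueScenario == "euploid"
  expect_equal(mc$trueCcf[eu], 2 * mc$trueF[eu])
  expect_true(all(mc$trueF[eu] <= 0.5))
  # roughly half the mutations fall in euploid territory
  expect_gt(mean(eu), 0.4); expect_lt(mean(eu), 0.6)
  # every aneuploid draw lies inside its scenario's zone (pre read noise)
  ov <- findOverlaps(v, segs, select = "first")
  for (i in which(!eu)) {
    j <- ov[i]
    b <- safBounds(mcols(segs)$nB[j], mcols(segs)$nT[j],
                   mcols(segs)$sAGP[j], mc$trueScenario[i])
    expect_true(mc$trueF[i] >= b[1] - 1e-12 && mc$trueF[i] <= b[2] + 1e-12)
  }
  # determinism under a fixed seed
  v2 <- simulateVariants(segs, nSnv = 2000L, coverage = 50, seed = 6)
  expect_identical(as.data.frame(v), as.data.frame(v2))
})

test_that("sAGP scoring reports zero error for perfect estimates", {
  segs <- simulateSegments(0.6, 0.2, sigmaBaf = 0, sigmaLrr = 0, seed = 7)
  mcols(segs)$nB <- mcols(segs)$trueNb
  mcols(segs)$nT <- mcols(segs)$trueNt
  mcols(segs)$sAGP <- mcols(segs)$trueP
  ev <- evaluateSagp(segs)
  expect_true(all(ev$stateErrorRate == 0))
  expect_true(all(ev$madAll == 0))
})

test_that("noise scaling degrades sAGP accuracy monotonically", {
  mads <- vapply(c(0.005, 0.02, 0.08), function(sb) {
    mean(vapply(1:3, function(s) {
      segs <- simulateSegments(0.8, 0.4, sigmaBaf = sb, sigmaLrr = 0.04,
                               seed = s)
      segs <- estimateSAGP(segs)
      ev <- evaluateSagp(segs)
      ev$madAll[ev$stratum == "all"]
    }, 1))
  }, 1)
  expect_true(all(diff(mads) > -1e-6))
})

test_that("CCF scoring is exact on perfect estimates and handles strata", {
  segs <- estimateSAGP(simulateSegments(0.8, 0.3, seed = 9))
  v <- simulateVariants(segs, nSnv = 300L, coverage = 50, seed = 10)
  mcols(v)$ccf <- mcols(v)$trueCcf
  sc <- evaluateCcf(v)
  expect_equal(sc$spearman, 1)
  expect_equal(sc$mad, 0)
  byType <- evaluateCcf(v, by = "hostType")
  expect_true("euploid" %in% byType$stratum)
  tiny <- evaluateCcf(v[1:2])
  expect_true(is.na(tiny$spearman))
})

test_that("the comparison protocol places ~half the mutations in sCNAs and
           the misspecified ablations fall behind the full model", {
  comp <- runComparisonProtocol(seed = 2, nMut = 600L)
  expect_gt(comp$nInScna / 600, 0.35)
  expect_lt(comp$nInScna / 600, 0.65)
  full <- comp$metrics$pearson
  expect_gt(full, comp$ablation[["ignoreR1"]])
  expect_gt(full, comp$ablation[["forceA1"]])
  expect_true(all(c("deletion", "cnloh", "amplification") %in%
                    sub(":.*", "", comp$byStratum$stratum)))
})
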