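# Fixture builders shared across tests. All fixtures are generated in code;
# nothing is read from disk except files these helpers write to tempdir().

# marker-level allele-count tables for a tumor/normal pair: `nChrom`
# chromosomes of `snpPerChrom` markers, with one sCNA planted in the middle
# third of each chromosome listed in `scnaChroms`
makeCountFixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                             nChrom = 12L, snpPerChrom = 150L,
                             scnaChroms = 2L, nB = 0L, nT = 2L, p = 0.8,
                             depth = 60, seed = 42L) {
  set.seed(seed)
  n <- nChrom * snpPerChrom
  chrom <- rep(paste0("chr", seq_len(nChrom)), each = snpPerChrom)
  pos <- as.vector(replicate(nChrom, sort(sample.int(5e6, snpPerChrom))))
  het <- runif(n) < 0.6
  gtB <- ifelse(het, 0.5, ifelse(runif(n) < 0.5, 0, 1))
  within <- rep(seq_len(snpPerChrom), nChrom)
  inScna <- chrom %in% paste0("chr", scnaChroms) &
    within > snpPerChrom / 3 & within <= 2 * snpPerChrom / 3
  nbar <- 2 * (1 - p) + nT * p
  bFrac <- ifelse(het & inScna, (p * nB + 1 - p) / nbar, gtB)
  tot <- ifelse(inScna, depth * nbar / 2, depth)
  aN <- round((1 - gtB) * depth + rnorm(n, 0, 1))
  bN <- round(gtB * depth + rnorm(n, 0, 1))
  aT <- round((1 - bFrac) * tot + rnorm(n, 0, 1))
  bT <- round(bFrac * tot + rnorm(n, 0, 1))
  clamp <- function(x) pmax(x, 0.1)
  writeTab <- function(a, b, path) {
    writeLines(c("SNP\tchrom\tpos\tA\tB",
                 sprintf("rs%d\t%s\t%d\t%.1f\t%.1f", seq_len(n), chrom, pos,
                         clamp(a), clamp(b))), path)
    path
  }
  list(tumor = writeTab(aT, bT, file.path(dir, "tumor.tsv")),
       normal = writeTab(aN, bN, file.path(dir, "normal.tsv")),
       chrom = chrom, pos = pos, het = het, inScna = inScna,
       p = p, nB = nB, nT = nT)
}

# minimal VCF 4.2 with tumor AD fields
makeVcfFixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                           records = data.frame(
                             chrom = "chr1", pos = c(1000L, 2000L, 3000L),
                             ref = c("A", "C", "G"), alt = c("T", "G", "A"),
                             adRef = c(60L, 30L, 80L),
                             adAlt = c(20L, 30L, 0L))) {
  path <- file.path(dir, "somatic.vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                  "Description=\"Allelic depths\">"),
           "##contig=<ID=chr1>",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "NORMAL", "TUMOR", sep = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD\t0/0:%d,0\t0/1:%d,%d",
                  records$chrom, records$pos, records$ref, records$alt,
                  records$adRef + records$adAlt, records$adRef, records$adAlt)
  writeLines(c(hdr, body), path)
  path
}

# brute-force SAF range from the three-subpopulation model: enumerate the
# free population fraction on a grid and track min/max attainable SAF
oracleSafRange <- function(nB, nT, p, scenario, by = 0.01) {
  nA <- nT - nB
  nbar <- 2 * (1 - p) + nT * p
  r1 <- seq(0, 1 - p, by = by)          # euploid mutation carriers (A/C)
  f <- switch(scenario,
    A1 = (r1 + nA * p) / nbar,
    A2 = if (nB >= 1) (r1 + nB * p) / nbar else r1 / nbar,
    B = seq(0, p, by = by) / nbar,      # mutated subset of sCNA cells
    C = r1 / nbar)
  c(min(f), max(f))
}

# scenario probability by adaptive numerical quadrature (independent of the
# closed-form incomplete-beta route)
oracleScenarioProb <- function(S, N, fl, fh) {
  if (fh <= fl) return(0)
  stats::integrate(function(f) dbinom(S, N, f), fl, fh,
                   rel.tol = 1e-12, abs.tol = 1e-14)$value
}
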