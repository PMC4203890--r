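# Input/output: allele-count tables, somatic variant counts, result tables.

#' Read a five-column allele-count table
#'
#' Parses a tab- (or whitespace-) delimited table with one row per SNP and the
#' fields: SNP ID, chromosome, position, A-allele count, B-allele count.
#' Counts may be real-valued (array intensities) or integer (read counts).
#' A header line is auto-detected. Malformed rows are dropped with a warning
#' naming their line numbers.
#'
#' @param path file path.
#' @return A [GenomicRanges::GRanges] sorted by (chrom, pos) with metadata
#'   columns `snpId`, `aCount`, `bCount`, and an attribute-free record of
#'   rejected rows in `metadata(gr)$nRejected`.
#' @export
readAlleleCounts <- function(path) {
  if (!file.exists(path)) stop("allele-count file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty allele-count file: ", path)
    gr <- GRanges()
    S4Vectors::metadata(gr)$nRejected <- 0L
    return(gr)
  }
  fields <- strsplit(lines, "[\t ]+")
  firstLine <- 1L
  f1 <- fields[[1L]]
  # header: position or count fields non-numeric
  if (length(f1) >= 5L &&
      (is.na(suppressWarnings(as.numeric(f1[3L]))) ||
       is.na(suppressWarnings(as.numeric(f1[4L])))))
    firstLine <- 2L
  rows <- fields[seq.int(firstLine, length(fields))]
  lineNo <- seq.int(firstLine, length(fields))
  nOk <- vapply(rows, length, 1L) >= 5L
  parse1 <- function(r) suppressWarnings(as.numeric(r[3:5]))
  num <- t(vapply(rows, function(r)
    if (length(r) >= 5L) parse1(r) else rep(NA_real_, 3L), numeric(3)))
  good <- nOk & !apply(is.na(num), 1L, any) &
    num[, 2L] >= 0 & num[, 3L] >= 0 & (num[, 2L] + num[, 3L]) > 0
  if (any(!good))
    warning(sum(!good), " malformed/unusable row(s) rejected at line(s): ",
            paste(head(lineNo[!good], 10L), collapse = ", "))
  rows <- rows[good]
  num <- num[good, , drop = FALSE]
  if (!nrow(num)) {
    gr <- GRanges()
    S4Vectors::metadata(gr)$nRejected <- sum(!good)
    return(gr)
  }
  chrom <- vapply(rows, `[`, "", 2L)
  gr <- GRanges(chrom, IRanges(start = as.integer(num[, 1L]), width = 1L),
                snpId = vapply(rows, `[`, "", 1L),
                aCount = num[, 2L], bCount = num[, 3L])
  gr <- GenomicRanges::sort(gr)
  dup <- duplicated(paste(seqnames(gr), start(gr)))
  if (any(dup)) {
    warning(sum(dup), " duplicate (chrom, pos) record(s) dropped")
    gr <- gr[!dup]
  }
  S4Vectors::metadata(gr)$nRejected <- sum(!good) + sum(dup)
  gr
}

#' Derive per-site BAF/LRR signals from a tumor/normal pair
#'
#' For each site shared by the tumor and normal tables, computes the tumor
#' B-allele fraction `baf = b_T/(a_T + b_T)`, the log R ratio
#' `lrr = log2((a_T + b_T)/(a_N + b_N))` (median-centered genome-wide so the
#' euploid mode sits near 0), and a germline heterozygosity call from the
#' normal BAF (within `0.5 +/- hetBand`). Sites with zero total signal in
#' either sample are dropped and counted.
#'
#' @param tumor,normal GRanges from [readAlleleCounts()].
#' @param hetBand half-width of the heterozygous BAF band (default 0.2).
#' @param centerLrr median-center LRR genome-wide (default TRUE).
#' @return GRanges with metadata columns `baf`, `lrr`, `isHet`.
#' @export
computeSiteSignals <- function(tumor, normal, hetBand = 0.2,
                               centerLrr = TRUE) {
  keyT <- paste(seqnames(tumor), start(tumor))
  keyN <- paste(seqnames(normal), start(normal))
  idx <- match(keyT, keyN)
  shared <- !is.na(idx)
  tum <- tumor[shared]
  nor <- normal[idx[shared]]
  totT <- mcols(tum)$aCount + mcols(tum)$bCount
  totN <- mcols(nor)$aCount + mcols(nor)$bCount
  ok <- totT > 0 & totN > 0
  if (any(!ok))
    message(sum(!ok), " site(s) dropped for zero total signal")
  tum <- tum[ok]; nor <- nor[ok]; totT <- totT[ok]; totN <- totN[ok]
  baf <- mcols(tum)$bCount / totT
  lrr <- log2(totT / totN)
  if (centerLrr && length(lrr)) lrr <- lrr - median(lrr)
  bafN <- mcols(nor)$bCount / totN
  out <- granges(tum)
  mcols(out) <- DataFrame(baf = baf, lrr = lrr,
                          isHet = abs(bafN - 0.5) <= hetBand)
  out
}

#' Read somatic variants with tumor allele depths
#'
#' Accepts either a VCF 4.x file carrying per-sample allele depths (`AD`) or a
#' tab-delimited fallback with columns chrom, pos, somatic-allele count S,
#' total depth N. Multi-allelic VCF records are skipped (logged); records with
#' zero depth are rejected and counted.
#'
#' @param path VCF (`.vcf`) or tabular file.
#' @param tumorSample sample name in the VCF; default is the last sample
#'   column (tumor conventionally follows normal).
#' @return GRanges with metadata columns `S` (somatic reads), `N` (depth),
#'   `saf` (= S/N).
#' @export
readSomaticVariants <- function(path, tumorSample = NULL) {
  if (!file.exists(path)) stop("variant file not found: ", path)
  isVcf <- grepl("\\.vcf(\\.gz|\\.bgz)?$", path, ignore.case = TRUE)
  if (isVcf) {
    vcf <- VariantAnnotation::readVcf(path)
    if (!"AD" %in% names(VariantAnnotation::geno(vcf)))
      stop("unsupported VCF: no per-sample AD (allele depth) field in ", path)
    samples <- colnames(vcf)
    if (is.null(tumorSample)) tumorSample <- samples[length(samples)]
    if (!tumorSample %in% samples)
      stop("tumor sample '", tumorSample, "' not found in VCF")
    nAlt <- lengths(VariantAnnotation::alt(vcf))
    multi <- nAlt > 1L
    if (any(multi))
      message(sum(multi), " multi-allelic record(s) skipped")
    vcf <- vcf[!multi]
    ad <- VariantAnnotation::geno(vcf)$AD[, tumorSample]
    refC <- vapply(ad, function(x) as.numeric(x[1L]), 1)
    altC <- vapply(ad, function(x) as.numeric(x[2L]), 1)
    gr <- granges(SummarizedExperiment::rowRanges(vcf))
    S <- altC; N <- refC + altC
  } else {
    tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 4L)
      stop("tabular somatic file needs >= 4 columns: chrom pos S N")
    if (is.na(suppressWarnings(as.numeric(tab[1L, 3L])))) tab <- tab[-1L, ]
    gr <- GRanges(as.character(tab[[1L]]),
                  IRanges(as.integer(tab[[2L]]), width = 1L))
    S <- as.numeric(tab[[3L]]); N <- as.numeric(tab[[4L]])
  }
  bad <- !is.finite(S) | !is.finite(N) | N < 1 | S < 0 | S > N
  if (any(bad))
    warning(sum(bad), " variant record(s) with unusable depths rejected")
  gr <- gr[!bad]
  S <- unname(S[!bad]); N <- unname(N[!bad])
  mcols(gr) <- DataFrame(S = as.integer(round(S)), N = as.integer(round(N)),
                         saf = ifelse(N > 0, S / N, NA_real_))
  names(gr) <- NULL
  GenomicRanges::sort(gr)
}

.fmtNum <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}

#' Write result tables and a run manifest
#'
#' Emits tab-delimited `segments.tsv` (per-segment copy state and sAGP, `NA`
#' where the regional mixing model failed), `variants.tsv` (per-mutation
#' scenario probabilities and CCF), `model_fit.tsv` (clonal-structure fit),
#' and `manifest.tsv` recording seed, software version and config.
#'
#' @param segments GRanges of fitted segments (may be NULL).
#' @param variants GRanges of CCF estimates (may be NULL).
#' @param modelFit a [ClonalModelFit-class] (may be NULL).
#' @param outDir output directory (created if needed).
#' @param config named list recorded in the manifest.
#' @param seed integer recorded in the manifest.
#' @return Invisibly, the vector of files written.
#' @export
writeResults <- function(segments = NULL, variants = NULL, modelFit = NULL,
                         outDir, config = list(), seed = NA_integer_) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  files <- character()
  if (!is.null(segments)) {
    df <- data.frame(
      chrom = as.character(seqnames(segments)),
      start = start(segments), end = end(segments),
      n_snps = mcols(segments)$nSnps,
      medLRR = .fmtNum(mcols(segments)$medLrr),
      medFoldedBAF = .fmtNum(mcols(segments)$medFbaf),
      n_b = ifelse(is.na(mcols(segments)$nB), "NA", mcols(segments)$nB),
      n_t = ifelse(is.na(mcols(segments)$nT), "NA", mcols(segments)$nT),
      sAGP = .fmtNum(mcols(segments)$sAGP))
    f <- file.path(outDir, "segments.tsv")
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(variants)) {
    mc <- mcols(variants)
    df <- data.frame(
      chrom = as.character(seqnames(variants)), pos = start(variants),
      S = mc$S, N = mc$N, f = .fmtNum(mc$saf),
      scenario_set = ifelse(is.na(mc$scenarioSet), "NA", mc$scenarioSet),
      p_A1 = .fmtNum(mc$pA1), p_A2 = .fmtNum(mc$pA2),
      p_B = .fmtNum(mc$pB), p_C = .fmtNum(mc$pC),
      CCF = .fmtNum(mc$ccf), CCF_exp = .fmtNum(mc$ccfExp),
      CCF_var = .fmtNum(mc$ccfVar))
    f <- file.path(outDir, "variants.tsv")
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(modelFit)) {
    cl <- clusterTable(modelFit)
    df <- data.frame(model = modelFit@model, n_peaks = modelFit@nPeaks,
                     peak = seq_len(nrow(cl)),
                     weight = .fmtNum(cl$weight), mean = .fmtNum(cl$mean),
                     sd = .fmtNum(cl$sd),
                     BIC_model1 = .fmtNum(unname(modelFit@bicAll["unimodal_uniform"])),
                     BIC_model2 = .fmtNum(unname(modelFit@bicAll["dp_mixture"])))
    f <- file.path(outDir, "model_fit.tsv")
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  cfg <- if (length(config)) yaml::as.yaml(config) else ""
  manifest <- data.frame(
    key = c("package", "version", "seed", "config"),
    value = c("subclonality", as.character(packageVersion("subclonality")),
              as.character(seed), gsub("\n", "; ", trimws(cfg))))
  f <- file.path(outDir, "manifest.tsv")
  write.table(manifest, f, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(files, f))
}
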