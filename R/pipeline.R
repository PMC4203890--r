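# End-to-end orchestration: read -> segment -> sAGP -> CCF -> clonal
# structure -> report.

#' Default pipeline configuration
#'
#' @param tumorCounts,normalCounts allele-count table paths.
#' @param somaticVariants optional VCF/tabular somatic file path.
#' @param outDir output directory.
#' @param unitKind "scna" (change-point segments) or "bin"; the default
#'   follows the guidance that CCF estimation should use sCNAs as the
#'   spatial unit, while bin mode suits exploratory clonal-structure runs.
#' @param seed integer seed.
#' @param ... overrides for nested module settings (hetBand, hetPerBin,
#'   minMarkers, alpha, nPerm, window, maxNt, thresholdMultiplier, metric,
#'   threshold, minDepth, minSaf, minValue, minBins, excludeChroms).
#' @return named list.
#' @export
pipelineConfig <- function(tumorCounts = NULL, normalCounts = NULL,
                           somaticVariants = NULL, outDir = "results",
                           unitKind = c("scna", "bin"), seed = 1L, ...) {
  cfg <- list(tumorCounts = tumorCounts, normalCounts = normalCounts,
              somaticVariants = somaticVariants, outDir = outDir,
              unitKind = match.arg(unitKind), seed = as.integer(seed),
              hetBand = 0.2, hetPerBin = 500L,
              minMarkers = 5L, alpha = 0.01, nPerm = 1000L, window = 5L,
              maxNt = 6L, thresholdMultiplier = 2, metric = "euclidean",
              threshold = 0.95, minDepth = 20L, minSaf = 0.05,
              minValue = 0.05, minBins = 50L,
              excludeChroms = c("chrX", "chrY", "X", "Y"))
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror [pipelineConfig()] arguments.
#' @return named list as from [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Reads the tumor/normal allele-count tables, derives site signals,
#' partitions the genome (bins or change-point sCNA segments), estimates
#' sAGP for every unit, estimates CCF for the somatic variants (when
#' provided), fits the clonal structure, and writes the result tables.
#'
#' @param config list from [pipelineConfig()] / [readPipelineConfig()].
#' @return list with `segments`, `variants`, `clonalFit`, `baseline`,
#'   `files`.
#' @export
runPipeline <- function(config) {
  set.seed(config$seed)
  if (is.null(config$tumorCounts) || is.null(config$normalCounts))
    stop("io_formats: tumorCounts and normalCounts paths are required")
  message("[io] reading allele counts")
  tum <- readAlleleCounts(config$tumorCounts)
  nor <- readAlleleCounts(config$normalCounts)
  sig <- computeSiteSignals(tum, nor, hetBand = config$hetBand)
  sig <- sig[!as.character(seqnames(sig)) %in% config$excludeChroms]
  message("[segmentation] ", length(sig), " sites, mode=", config$unitKind)
  segs <- if (config$unitKind == "bin")
    makeBins(sig, hetPerBin = config$hetPerBin)
  else
    segmentGenome(sig, minMarkers = config$minMarkers,
                  alpha = config$alpha, nPerm = config$nPerm,
                  window = config$window)
  message("[sagp] fitting ", length(segs), " segments")
  segs <- estimateSAGP(segs, maxNt = config$maxNt,
                       thresholdMultiplier = config$thresholdMultiplier,
                       metric = config$metric)
  variants <- NULL
  if (!is.null(config$somaticVariants)) {
    message("[ccf] estimating variant cell fractions")
    variants <- readSomaticVariants(config$somaticVariants)
    variants <- estimateCCF(variants, segs, threshold = config$threshold,
                            minDepth = config$minDepth,
                            minSaf = config$minSaf)
  }
  message("[clonal] fitting clonal structure")
  clonalFit <- tryCatch(
    fitClonalStructure(segs, minValue = config$minValue,
                       minBins = config$minBins, seed = config$seed),
    warning = function(w) { message("  ", conditionMessage(w)); NULL })
  files <- writeResults(segs, variants, clonalFit, config$outDir,
                        config = config, seed = config$seed)
  list(segments = segs, variants = variants, clonalFit = clonalFit,
       baseline = S4Vectors::metadata(segs)$baseline, files = files)
}

#' Run the in-silico validation suite
#'
#' Reproduces the package's benchmark metrics: the dominant/minor sAGP grid
#' (optionally subsampled), the CCF validation cases at the configured
#' coverages, and the comparison protocol.
#'
#' @param seed integer seed.
#' @param gridStep step of the (pDom, pSub) grid to run (default 0.1; use a
#'   larger step for a quick pass).
#' @param coverages depths for the CCF validation (default c(50, 100)).
#' @param nSnv variants per CCF case.
#' @return list with `sagpGridMetrics`, `ccfValidation`, `comparison`.
#' @export
runValidationSuite <- function(seed = 1L, gridStep = 0.1,
                               coverages = c(50, 100), nSnv = 4000L) {
  grid <- sagpGrid(gridStep)
  gm <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    segs <- simulateSegments(grid$pDom[i], grid$pSub[i],
                             seed = (seed * 101L + i) %%
                               .Machine$integer.max)
    segs <- estimateSAGP(segs)
    ev <- evaluateSagp(segs)
    cbind(pDom = grid$pDom[i], pSub = grid$pSub[i], ev)
  }))
  ccf <- runCcfValidation(coverages = coverages, nSnv = nSnv, seed = seed)
  comp <- runComparisonProtocol(seed = seed)
  list(sagpGridMetrics = gm, ccfValidation = ccf,
       comparison = list(metrics = comp$metrics, ablation = comp$ablation,
                         nInScna = comp$nInScna))
}
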