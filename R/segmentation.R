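# Genome partitioning: fixed het-SNP bins, or change-point segments on LRR
# and folded BAF with the within-window merge rule.

#' Partition heterozygous markers into fixed-size bins
#'
#' Consecutive runs of `hetPerBin` germline-heterozygous markers define a bin
#' on each chromosome. All markers (het and hom) inside a bin contribute to
#' its median LRR; only het markers contribute to the median folded BAF. A
#' trailing partial bin is kept if it holds at least `hetPerBin/2` het
#' markers, otherwise it is merged into the previous bin. A chromosome with
#' fewer than `hetPerBin/2` het markers becomes a single whole-chromosome bin
#' (with a warning).
#'
#' @param signals GRanges from [computeSiteSignals()].
#' @param hetPerBin het markers per bin (default 500, minimum 50).
#' @return GRanges of bins with columns `nSnps`, `medLrr`, `medFbaf`,
#'   `unitKind = "bin"`.
#' @export
makeBins <- function(signals, hetPerBin = 500L) {
  stopifnot(hetPerBin >= 50L)
  out <- list()
  for (chr in unique(as.character(seqnames(signals)))) {
    s <- signals[seqnames(signals) == chr]
    het <- mcols(s)$isHet
    nHet <- sum(het)
    if (nHet < hetPerBin / 2) {
      warning("chromosome ", chr, " has ", nHet,
              " het markers; using one whole-chromosome bin")
      binOf <- rep(1L, length(s))
    } else {
      # bin index by cumulative het count; hom markers inherit the bin of
      # the enclosing het run
      hetIdx <- cumsum(het)
      binOf <- pmax(1L, ceiling(pmin(hetIdx + !het, nHet) / hetPerBin))
      nBins <- max(binOf)
      lastHet <- nHet - (nBins - 1L) * hetPerBin
      if (nBins > 1L && lastHet < hetPerBin / 2)
        binOf[binOf == nBins] <- nBins - 1L
    }
    out[[chr]] <- .summarizeByGroup(s, binOf, "bin")
  }
  do.call(c, unname(out))
}

.summarizeByGroup <- function(s, group, unitKind) {
  idx <- split(seq_along(s), group)
  res <- lapply(idx, function(i) {
    het <- mcols(s)$isHet[i]
    fb <- abs(mcols(s)$baf[i][het] - 0.5)
    data.frame(
      start = min(start(s)[i]), end = max(start(s)[i]),
      nSnps = length(i),
      medLrr = median(mcols(s)$lrr[i]),
      medFbaf = if (length(fb)) median(fb) else NA_real_)
  })
  df <- do.call(rbind, res)
  GRanges(as.character(seqnames(s))[1L], IRanges(df$start, df$end),
          nSnps = df$nSnps, medLrr = df$medLrr, medFbaf = df$medFbaf,
          unitKind = unitKind)
}

#' Recursive binary change-point detection
#'
#' Binary segmentation in the spirit of circular binary segmentation: within
#' each interval the split maximizing the standardized mean-difference
#' statistic between the two resulting arcs is accepted when its permutation
#' p-value falls below `alpha`; recursion stops when no split is significant
#' or a resulting piece would hold fewer than `minMarkers` markers.
#'
#' @param values numeric series (one chromosome's markers, in order).
#' @param minMarkers minimum markers per segment (default 5).
#' @param alpha significance level for a split (default 0.01).
#' @param nPerm permutations per test (default 1000).
#' @return Integer vector of change points; change point `i` means a new
#'   segment starts at marker `i + 1`. Empty when no split is significant.
#' @export
detectChangepoints <- function(values, minMarkers = 5L, alpha = 0.01,
                               nPerm = 1000L) {
  n <- length(values)
  if (n < 2L * minMarkers || all(values == values[1L])) return(integer())
  .splitRec <- function(lo, hi) {
    m <- hi - lo + 1L
    if (m < 2L * minMarkers) return(integer())
    x <- values[lo:hi]
    obs <- .maxSplitStat(x, minMarkers)
    if (is.na(obs$stat)) return(integer())
    permStats <- vapply(seq_len(nPerm), function(i)
      .maxSplitStat(x[sample.int(m)], minMarkers)$stat, 1)
    pval <- (1 + sum(permStats >= obs$stat, na.rm = TRUE)) / (1 + nPerm)
    if (pval >= alpha) return(integer())
    cp <- lo + obs$at - 1L
    sort(c(.splitRec(lo, cp), cp, .splitRec(cp + 1L, hi)))
  }
  .splitRec(1L, n)
}

# max over candidate splits of |mean1 - mean2| / (s * sqrt(1/n1 + 1/n2));
# first maximal statistic wins ties
.maxSplitStat <- function(x, minMarkers) {
  m <- length(x)
  ks <- seq.int(minMarkers, m - minMarkers)
  if (!length(ks)) return(list(stat = NA_real_, at = NA_integer_))
  cs <- cumsum(x)
  tot <- cs[m]
  m1 <- cs[ks] / ks
  m2 <- (tot - cs[ks]) / (m - ks)
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(list(stat = NA_real_, at = NA_integer_))
  stat <- abs(m1 - m2) / (s * sqrt(1 / ks + 1 / (m - ks)))
  i <- which.max(stat)
  list(stat = stat[i], at = ks[i])
}

#' Merge LRR and folded-BAF change points
#'
#' Every BAF change point within `window` markers (either direction) of some
#' LRR change point is removed — the two are assumed to capture the same
#' event, with the BAF placement less precise due to het-marker sparsity. The
#' result is the union of all LRR change points and the surviving BAF change
#' points.
#'
#' @param lrrCps,bafCps sorted integer change-point indices.
#' @param window marker distance (default 5).
#' @return Sorted merged indices.
#' @export
mergeChangepoints <- function(lrrCps, bafCps, window = 5L) {
  if (!length(bafCps)) return(sort(unique(as.integer(lrrCps))))
  keep <- vapply(bafCps, function(b)
    !length(lrrCps) || min(abs(lrrCps - b)) > window, TRUE)
  sort(unique(as.integer(c(lrrCps, bafCps[keep]))))
}

#' Summarize marker signals over segments
#'
#' Computes per segment the median LRR over all markers and the median folded
#' BAF (`median |BAF - 0.5|`) over het markers. Segments with zero het
#' markers carry a missing `medFbaf` (excluded from sAGP fitting).
#'
#' @param signals GRanges from [computeSiteSignals()].
#' @param changepoints named list of integer vectors (per chromosome) as from
#'   [detectChangepoints()] / [mergeChangepoints()], or NULL for one segment
#'   per chromosome.
#' @param unitKind label stored on the segments (default "scna").
#' @return GRanges of segments with `nSnps`, `medLrr`, `medFbaf`, `unitKind`.
#' @export
summarizeSegments <- function(signals, changepoints = NULL,
                              unitKind = "scna") {
  out <- list()
  for (chr in unique(as.character(seqnames(signals)))) {
    s <- signals[seqnames(signals) == chr]
    cps <- changepoints[[chr]]
    bounds <- c(0L, sort(unique(cps)), length(s))
    group <- rep(seq_len(length(bounds) - 1L), diff(bounds))
    out[[chr]] <- .summarizeByGroup(s, group, unitKind)
  }
  do.call(c, unname(out))
}

#' Segment a sample end to end
#'
#' Runs change-point detection independently on LRR (all markers) and folded
#' BAF (het markers), maps BAF change points back to all-marker indices,
#' merges them with the 5-marker rule, and summarizes the resulting segments.
#'
#' @inheritParams detectChangepoints
#' @param signals GRanges from [computeSiteSignals()].
#' @param window merge window in markers (default 5).
#' @return GRanges of sCNA segments.
#' @export
segmentGenome <- function(signals, minMarkers = 5L, alpha = 0.01,
                          nPerm = 1000L, window = 5L) {
  cps <- list()
  for (chr in unique(as.character(seqnames(signals)))) {
    s <- signals[seqnames(signals) == chr]
    lrrCp <- detectChangepoints(mcols(s)$lrr, minMarkers, alpha, nPerm)
    hetIdx <- which(mcols(s)$isHet)
    bafCp <- integer()
    if (length(hetIdx) >= 2L * minMarkers) {
      fb <- abs(mcols(s)$baf[hetIdx] - 0.5)
      bafCpHet <- detectChangepoints(fb, minMarkers, alpha, nPerm)
      bafCp <- hetIdx[bafCpHet]
    }
    cps[[chr]] <- mergeChangepoints(lrrCp, bafCp, window)
  }
  summarizeSegments(signals, cps, unitKind = "scna")
}
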