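## Seedable emulation of the three caller styles from a ground-truth CNV
## profile.  Reads are never simulated: each emulator reproduces the
## statistical signature the consensus model assumes for its role (the
## coverage caller's integer-CN bias peaks, the hybrid caller's
## exponentially growing null-ratio distortion and prediction gaps, the
## referee caller's correct direction with wild magnitudes).

#' Simulate a ground-truth CNV profile
#'
#' Per chromosome, between 30 and 50 non-overlapping CNV segments are placed,
#' each with a length uniform in [10 kbp, 100 kbp] and a copy number drawn
#' from \{0, 1, 3, 4, ..., 8\} (never the diploid 2); the background between
#' segments is at copy number 2.  Segments are separated by at least
#' \code{minGap} bases.
#'
#' @param nChroms number of chromosomes (named "1", "2", ...).
#' @param chromLength chromosome length in bp.
#' @param seed integer RNG seed (\code{NULL} = leave the RNG state alone).
#' @param segmentsPerChrom integer length-2 range of CNV segment counts.
#' @param lengthRange integer length-2 range of segment lengths (bp).
#' @param cnLevels copy numbers to draw from.
#' @param minGap minimum gap between segments (bp).
#' @return GRanges with metadata column \code{trueCN}.
#' @examples
#' truth <- simulateTruth(seed = 1)
#' @export
simulateTruth <- function(nChroms = 1L, chromLength = 1e7, seed = NULL,
                          segmentsPerChrom = c(30L, 50L),
                          lengthRange = c(1e4, 1e5),
                          cnLevels = c(0, 1, 3:8), minGap = 1000L) {
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", nChroms)
  for (ch in seq_len(nChroms)) {
    n <- sample(segmentsPerChrom[1]:segmentsPerChrom[2], 1L)
    len <- round(runif(n, lengthRange[1], lengthRange[2]))
    free <- chromLength - sum(len) - (n + 1L) * minGap
    if (free < 0)
      stop(sprintf("chromosome length %g cannot host %d segments totalling %g bp",
                   chromLength, n, sum(len)))
    ## split the free space into n+1 random gaps added on top of minGap
    cuts <- sort(runif(n, 0, free))
    gaps <- diff(c(0, cuts, free)) + minGap   # n + 1 gaps; the last follows the final segment
    start <- cumsum(gaps[seq_len(n)]) + cumsum(c(0, len[-n])) + 1
    cn <- sample(cnLevels, n, replace = TRUE)
    gr <- GenomicRanges::GRanges(as.character(ch),
                                 IRanges::IRanges(as.integer(start),
                                                  as.integer(start + len - 1)))
    S4Vectors::mcols(gr)$trueCN <- cn
    out[[ch]] <- gr
  }
  sortByCoord(bindGR(out))
}

## True copy number of fixed-width bins tiling [1, chromLength] per
## chromosome: length-weighted mean of the truth profile across each bin
## (background at `background`).
.binnedTruth <- function(truth, chroms, chromLength, binSize,
                         background = 2) {
  bins <- bindGR(lapply(chroms, function(ch) {
    s <- seq(1L, chromLength, by = binSize)
    GenomicRanges::GRanges(ch, IRanges::IRanges(
      as.integer(s), as.integer(pmin(s + binSize - 1, chromLength))))
  }))
  v <- rep(as.numeric(background), length(bins))
  ov <- GenomicRanges::findOverlaps(bins, truth)
  if (length(ov)) {
    w <- GenomicRanges::width(GenomicRanges::pintersect(
      bins[S4Vectors::queryHits(ov)], truth[S4Vectors::subjectHits(ov)]))
    dev <- (S4Vectors::mcols(truth)$trueCN[S4Vectors::subjectHits(ov)] -
              background) * w
    adj <- tapply(dev, S4Vectors::queryHits(ov), sum)
    idx <- as.integer(names(adj))
    v[idx] <- v[idx] + as.numeric(adj) / GenomicRanges::width(bins)[idx]
  }
  S4Vectors::mcols(bins)$value <- v
  bins
}

#' Emulate a gap-free coverage caller
#'
#' Tiles every chromosome with fixed-size bins and reports, per bin, the true
#' copy number shifted by \code{-peakShift} (the systematic bias whose
#' frequency peak \code{\link{estimateBias}} recovers) plus Gaussian noise,
#' floored at 0.  The output covers every base (coverage callers predict
#' gap-free).
#'
#' @param truth GRanges with \code{trueCN} (see \code{\link{simulateTruth}}).
#' @param chromLength chromosome length used to tile (bp).
#' @param binSize bin width in bp (default 450, a typical post-segmentation
#'   average).
#' @param noiseSD Gaussian noise standard deviation (CN units).
#' @param peakShift systematic shift subtracted from every bin (CN units).
#' @param seed integer RNG seed.
#' @return a coverage \linkS4class{CallerTrack}.
#' @export
emulateCoverageCaller <- function(truth, chromLength = 1e7, binSize = 450L,
                                  noiseSD = 0.5, peakShift = 0.1,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- unique(as.character(GenomicRanges::seqnames(truth)))
  bins <- .binnedTruth(truth, chroms, chromLength, binSize)
  v <- S4Vectors::mcols(bins)$value - peakShift
  if (noiseSD > 0) v <- v + rnorm(length(v), 0, noiseSD)
  S4Vectors::mcols(bins)$value <- pmax(v, 0)
  trackFromGRanges(bins, "coverage", "absolute_cn")
}

#' Emulate a hybrid caller reporting ratios against a null alignment
#'
#' The emitted value \code{y} per bin solves \code{y * q(y) = trueCN}, i.e.
#' it is the numerical inverse of the equalizer correction
#' (\code{\link{equalizeNullRatio}}), so the distortion grows exponentially
#' with the true amplification exactly as the correction assumes.  Gaussian
#' noise is added on the reported scale (truncated at 0) and a fraction
#' \code{gapRate} of bins is dropped at random (hybrid callers do not
#' predict gap-free).
#'
#' @inheritParams emulateCoverageCaller
#' @param binSize bin width in bp (default 400).
#' @param gapRate fraction of bins dropped, in [0, 1).
#' @return a hybrid \linkS4class{CallerTrack} with
#'   \code{valueScale = "ratio_vs_null"}.
#' @export
emulateHybridCaller <- function(truth, chromLength = 1e7, binSize = 400L,
                                gapRate = 0.3, noiseSD = 0.5, seed = NULL) {
  stopifnot(gapRate >= 0, gapRate < 1)
  if (!is.null(seed)) set.seed(seed)
  chroms <- unique(as.character(GenomicRanges::seqnames(truth)))
  bins <- .binnedTruth(truth, chroms, chromLength, binSize)
  y <- invertEqualizer(S4Vectors::mcols(bins)$value)
  if (noiseSD > 0) y <- pmax(y + rnorm(length(y), 0, noiseSD), 0)
  S4Vectors::mcols(bins)$value <- y
  if (gapRate > 0) bins <- bins[runif(length(bins)) >= gapRate]
  trackFromGRanges(bins, "hybrid", "ratio_vs_null")
}

#' Emulate a referee caller: correct direction, unreliable magnitude
#'
#' Calls a random subset of the true CNV segments.  The emitted class
#' (deletion below ploidy, amplification above) is always correct, but the
#' magnitude is multiplied by a heavy-tailed factor of up to
#' \code{magnitudeScale} (amplifications are inflated away from the ploidy,
#' deletions deflated towards 0), emulating callers whose amplification
#' copy numbers can reach the tens of thousands.
#'
#' @param truth GRanges with \code{trueCN}.
#' @param gapRate fraction of true segments left uncalled, in [0, 1].
#' @param magnitudeScale upper bound of the random magnitude factor (>= 1).
#' @param P ploidy of the truth background.
#' @param seed integer RNG seed.
#' @return a referee \linkS4class{CallerTrack}.
#' @export
emulateRefereeCaller <- function(truth, gapRate = 0.5,
                                 magnitudeScale = 1000, P = 2,
                                 seed = NULL) {
  stopifnot(gapRate >= 0, gapRate <= 1, magnitudeScale >= 1)
  if (!is.null(seed)) set.seed(seed)
  keep <- runif(length(truth)) >= gapRate
  seg <- truth[keep]
  n <- length(seg)
  f <- if (magnitudeScale > 1 && n)
    pmin(exp(rexp(n, rate = 3 / log(magnitudeScale))), magnitudeScale)
  else rep(1, n)
  cn <- S4Vectors::mcols(seg)$trueCN
  amp <- cn > P
  v <- numeric(n)
  v[amp] <- P + (cn[amp] - P) * f[amp]     # inflated, stays above ploidy
  v[!amp] <- cn[!amp] / f[!amp]            # deflated, stays below ploidy
  gr <- GenomicRanges::granges(seg)
  S4Vectors::mcols(gr)$value <- v
  trackFromGRanges(gr, "referee", "absolute_cn")
}

## Non-overlapping gene models tiled with random lengths/gaps, plus the truth
## table obtained by length-weighted mapping of the truth profile.
.simulateGenes <- function(truth, chroms, chromLength, nGenes = 200L,
                           lengthRange = c(2e3, 2e4), ploidyModel) {
  out <- vector("list", length(chroms))
  for (k in seq_along(chroms)) {
    len <- round(runif(nGenes, lengthRange[1], lengthRange[2]))
    free <- chromLength - sum(len) - (nGenes + 1L)
    if (free < 0) stop("chromosome too short for the requested gene set")
    cuts <- sort(runif(nGenes, 0, free))
    gaps <- diff(c(0, cuts, free)) + 1
    start <- cumsum(gaps[seq_len(nGenes)]) + cumsum(c(0, len[-nGenes])) + 1
    gr <- GenomicRanges::GRanges(chroms[k],
                                 IRanges::IRanges(as.integer(start),
                                                  as.integer(start + len - 1)))
    S4Vectors::mcols(gr)$gene_id <-
      sprintf("gene_%s_%04d", chroms[k], seq_len(nGenes))
    out[[k]] <- gr
  }
  genes <- sortByCoord(bindGR(out))
  trueCN <- mapSegmentsToGenes(
    {
      seg <- truth
      S4Vectors::mcols(seg)$cnMeta <- S4Vectors::mcols(seg)$trueCN
      seg
    }, genes, ploidyModel)
  list(genes = genes,
       truthTable = data.frame(gene_id = names(trueCN),
                               true_cn = as.numeric(trueCN),
                               stringsAsFactors = FALSE))
}

#' Generate a complete synthetic calling scenario
#'
#' Draws a ground-truth CNV profile, emulates the three caller tracks from
#' it, and generates a non-overlapping gene set with its per-gene truth
#' table.  Fully deterministic for a fixed seed and configuration.
#'
#' @param seed integer RNG seed.
#' @param nChroms,chromLength truth profile dimensions.
#' @param coverageNoiseSD,peakShift coverage emulator parameters.
#' @param hybridNoiseSD,hybridGapRate hybrid emulator parameters.
#' @param refereeGapRate,magnitudeScale referee emulator parameters.
#' @param nGenes genes per chromosome.
#' @param segmentsPerChrom,lengthRange truth profile design (see
#'   \code{\link{simulateTruth}}); scale these down together with
#'   \code{chromLength} for small test scenarios.
#' @param ploidyModel a \linkS4class{PloidyModel}.
#' @return a \linkS4class{SyntheticScenario}.
#' @examples
#' sc <- simulateScenario(seed = 1, chromLength = 2e6, nGenes = 50,
#'                        segmentsPerChrom = c(10L, 20L),
#'                        lengthRange = c(5e3, 3e4))
#' @export
simulateScenario <- function(seed, nChroms = 1L, chromLength = 1e7,
                             coverageNoiseSD = 0.5, peakShift = 0.1,
                             hybridNoiseSD = 0.5, hybridGapRate = 0.3,
                             refereeGapRate = 0.5, magnitudeScale = 1000,
                             nGenes = 200L,
                             segmentsPerChrom = c(30L, 50L),
                             lengthRange = c(1e4, 1e5),
                             ploidyModel = PloidyModel()) {
  seed <- as.integer(seed)
  set.seed(seed)
  truth <- simulateTruth(nChroms, chromLength,
                         segmentsPerChrom = segmentsPerChrom,
                         lengthRange = lengthRange)
  chroms <- unique(as.character(GenomicRanges::seqnames(truth)))
  coverage <- emulateCoverageCaller(truth, chromLength,
                                    noiseSD = coverageNoiseSD,
                                    peakShift = peakShift)
  hybrid <- emulateHybridCaller(truth, chromLength,
                                gapRate = hybridGapRate,
                                noiseSD = hybridNoiseSD)
  referee <- emulateRefereeCaller(truth, gapRate = refereeGapRate,
                                  magnitudeScale = magnitudeScale,
                                  P = ploidyModel@defaultPloidy)
  gg <- .simulateGenes(truth, chroms, chromLength, nGenes,
                       ploidyModel = ploidyModel)
  new("SyntheticScenario", seed = seed, truth = truth, coverage = coverage,
      hybrid = hybrid, referee = referee, genes = gg$genes,
      truthTable = gg$truthTable)
}

setMethod("show", "SyntheticScenario", function(object) {
  cat(sprintf("SyntheticScenario (seed %d): %d truth segment(s), %d gene(s)\n",
              object@seed, length(object@truth), length(object@genes)))
  cat(sprintf("  coverage %d bins / hybrid %d bins / referee %d call(s)\n",
              length(object@coverage), length(object@hybrid),
              length(object@referee)))
  invisible(NULL)
})

#' Hand-built six-bin rule demonstration scenario
#'
#' A deterministic fixture of seven 1-kb bins (a-g) on one chromosome that
#' exercises every headline consensus rule: c (both callers amplified) and d
#' (both deleted) agree; f is amplified by the coverage caller with a hybrid
#' gap; e and g are coverage/hybrid class conflicts arbitrated to
#' amplification by the referee; b is a conflict without a referee call and
#' is set to the ploidy.  The config carried in the scenario fixes bias 0 and
#' thresholds T1 = 1.85 / T2 = 2.15 so the demonstration is independent of
#' histogram estimation.
#'
#' @return a list with elements \code{coverage}, \code{hybrid},
#'   \code{referee} (\linkS4class{CallerTrack}s), \code{config}
#'   (a \code{\link{consensusConfig}}), \code{bins} (named GRanges of the
#'   seven input bins) and \code{expectedClass} (named character vector of
#'   the expected consensus class per bin).
#' @examples
#' fx <- makeRuleScenario()
#' segs <- callConsensus(fx$coverage, fx$hybrid, fx$referee,
#'                       config = fx$config)
#' @export
makeRuleScenario <- function() {
  binStart <- seq(1L, 6001L, by = 1000L)
  binEnd <- binStart + 999L
  labels <- letters[1:7]
  coverage <- CallerTrack(rep("1", 7), binStart, binEnd,
                          value = c(2, 4, 4, 0.9, 2, 4, 4),
                          "coverage", "absolute_cn")
  ## hybrid makes no prediction on bin f (index 6)
  hybIdx <- c(1:5, 7)
  hybrid <- CallerTrack(rep("1", 6), binStart[hybIdx], binEnd[hybIdx],
                        value = c(2, 2, 4, 0.9, 4, 2),
                        "hybrid", "ratio_vs_null")
  ## referee calls amplifications on the conflicting bins e and g only
  referee <- CallerTrack(rep("1", 2), binStart[c(5, 7)], binEnd[c(5, 7)],
                         value = c(44084, 44084),
                         "referee", "absolute_cn")
  bins <- GenomicRanges::GRanges("1", IRanges::IRanges(binStart, binEnd))
  names(bins) <- labels
  list(coverage = coverage, hybrid = hybrid, referee = referee,
       config = consensusConfig(bias = 0, thresholds = Thresholds(2.15)),
       bins = bins,
       expectedClass = c(a = "normal", b = "normal", c = "amplification",
                         d = "deletion", e = "amplification",
                         f = "amplification", g = "amplification"))
}
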