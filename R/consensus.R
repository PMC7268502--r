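#' Partition the genome on the union of all callers' breakpoints
#'
#' Every interval endpoint of every input track becomes a breakpoint; the
#' resulting bins tile the covered extent without overlap, and each bin lies
#' strictly inside or strictly outside every original interval, so a track
#' contributes its value to a bin exactly when the bin is within one of its
#' intervals.
#'
#' @param tracks named list of \linkS4class{CallerTrack}s.
#' @return a GRanges of bins with one metadata column per track (the track's
#'   value on the bin, \code{NA} where the track makes no prediction) and,
#'   for tracks carrying class labels, a \code{<name>_class} column.
#' @examples
#' cov <- CallerTrack(c("1", "1"), c(1, 101), c(100, 200), c(2, 2),
#'                    "coverage", "absolute_cn")
#' hyb <- CallerTrack("1", 1, 150, 2, "hybrid", "ratio_vs_null")
#' unionBreakpoints(list(rd = cov, sv = hyb))
#' @export
unionBreakpoints <- function(tracks) {
  stopifnot(length(tracks) >= 1L, !is.null(names(tracks)))
  grl <- lapply(tracks, function(t) GenomicRanges::granges(t@calls))
  bins <- GenomicRanges::disjoin(bindGR(unname(grl)))
  bins <- sortByCoord(bins)
  for (nm in names(tracks)) {
    cl <- tracks[[nm]]@calls
    ov <- GenomicRanges::findOverlaps(bins, cl, type = "within")
    v <- rep(NA_real_, length(bins))
    v[S4Vectors::queryHits(ov)] <-
      S4Vectors::mcols(cl)$value[S4Vectors::subjectHits(ov)]
    S4Vectors::mcols(bins)[[nm]] <- v
    if ("svClass" %in% colnames(S4Vectors::mcols(cl))) {
      k <- rep(NA_character_, length(bins))
      k[S4Vectors::queryHits(ov)] <-
        S4Vectors::mcols(cl)$svClass[S4Vectors::subjectHits(ov)]
      S4Vectors::mcols(bins)[[paste0(nm, "_class")]] <- k
    }
  }
  bins
}

#' Classify a copy number against the T1/T2 thresholds
#'
#' @param cn numeric vector of absolute copy numbers (\code{NA} allowed).
#' @param thresholds a \linkS4class{Thresholds}.
#' @return character vector: \code{"deletion"} (cn < T1), \code{"normal"}
#'   (T1 <= cn <= T2) or \code{"amplification"} (cn > T2); \code{NA} in,
#'   \code{NA} out.
#' @examples
#' classifyCN(c(1.5, 2.0, 2.4), Thresholds(2.15))
#' @export
classifyCN <- function(cn, thresholds) {
  stopifnot(is(thresholds, "Thresholds"))
  out <- rep(NA_character_, length(cn))
  out[!is.na(cn) & cn < thresholds@t1] <- "deletion"
  out[!is.na(cn) & cn >= thresholds@t1 & cn <= thresholds@t2] <- "normal"
  out[!is.na(cn) & cn > thresholds@t2] <- "amplification"
  out
}

#' Direction judged by the referee caller
#'
#' The referee's magnitudes are unreliable; only the direction relative to
#' the ploidy is used.  Explicit class labels pass through; numeric values
#' below the ploidy mean deletion, above it amplification; a value exactly at
#' the ploidy, or no prediction at all, gives \code{"none"}.
#'
#' @param value numeric vector of referee values (\code{NA} = no prediction
#'   or class-only call).
#' @param P ploidy (scalar or vector).
#' @param svClass optional character vector of explicit labels
#'   (\code{"deletion"} / \code{"amplification"} / \code{"duplication"}).
#' @return character vector over \code{c("deletion", "amplification",
#'   "none")}.
#' @examples
#' refereeClass(c(44084, 0, NA), P = 2)
#' @export
refereeClass <- function(value, P = 2, svClass = NULL) {
  n <- length(value)
  P <- rep_len(P, n)
  out <- rep("none", n)
  num <- !is.na(value)
  out[num & value < P] <- "deletion"
  out[num & value > P] <- "amplification"
  if (!is.null(svClass)) {
    svClass <- as.character(svClass)
    svClass[svClass == "duplication"] <- "amplification"
    lab <- !is.na(svClass)
    out[lab] <- svClass[lab]
  }
  out
}

#' Decide the consensus copy number of one bin
#'
#' Applies the consensus rule table.  Deletions and normal copy numbers are
#' accepted from the coverage caller, amplifications from the hybrid caller;
#' a caller absent from the bin leaves the other caller's call standing; a
#' class conflict is arbitrated by the referee, whose class selects the
#' matching caller's value; a conflict the referee cannot resolve (no
#' prediction, or a class matching neither caller) sets the bin to the
#' ploidy.  The referee never contributes a numeric value.
#'
#' All arguments are vectorised over bins.
#'
#' @param cnRd coverage caller's harmonised CN (\code{NA} = absent).
#' @param cnSv hybrid caller's harmonised CN (\code{NA} = absent).
#' @param referee referee class per bin (\code{"deletion"},
#'   \code{"amplification"} or \code{"none"}).
#' @param thresholds a \linkS4class{Thresholds}.
#' @param P ploidy (scalar or per-bin vector).
#' @return a data.frame with columns \code{cnMeta} (numeric) and
#'   \code{ruleId} (character; one of agree_deletion, agree_normal,
#'   agree_amplification, coverage_only, hybrid_only, referee_coverage,
#'   referee_hybrid, conflict_no_referee, referee_mismatch, no_evidence).
#' @examples
#' th <- Thresholds(2.15)
#' decideBin(cnRd = 4, cnSv = 2, referee = "none", th, P = 2)     # -> 2
#' decideBin(cnRd = 4, cnSv = 2, referee = "amplification", th, 2) # -> 4
#' @export
decideBin <- function(cnRd, cnSv, referee = "none",
                      thresholds = Thresholds(2.15), P = 2) {
  n <- max(length(cnRd), length(cnSv), length(referee))
  cnRd <- rep_len(cnRd, n); cnSv <- rep_len(cnSv, n)
  referee <- rep_len(referee, n); P <- rep_len(P, n)
  clsRd <- classifyCN(cnRd, thresholds)
  clsSv <- classifyCN(cnSv, thresholds)
  cnMeta <- rep(NA_real_, n)
  ruleId <- rep(NA_character_, n)

  bothAbsent <- is.na(cnRd) & is.na(cnSv)
  rdOnly <- !is.na(cnRd) & is.na(cnSv)
  svOnly <- is.na(cnRd) & !is.na(cnSv)
  both <- !is.na(cnRd) & !is.na(cnSv)
  agree <- both & clsRd == clsSv
  conflict <- both & clsRd != clsSv

  cnMeta[bothAbsent] <- P[bothAbsent]; ruleId[bothAbsent] <- "no_evidence"
  cnMeta[rdOnly] <- cnRd[rdOnly];      ruleId[rdOnly] <- "coverage_only"
  cnMeta[svOnly] <- cnSv[svOnly];      ruleId[svOnly] <- "hybrid_only"

  aAmp <- agree & clsRd == "amplification"
  cnMeta[aAmp] <- cnSv[aAmp]; ruleId[aAmp] <- "agree_amplification"
  aDel <- agree & clsRd == "deletion"
  cnMeta[aDel] <- cnRd[aDel]; ruleId[aDel] <- "agree_deletion"
  aNor <- agree & clsRd == "normal"
  cnMeta[aNor] <- cnRd[aNor]; ruleId[aNor] <- "agree_normal"

  refRd <- conflict & referee == clsRd
  cnMeta[refRd] <- cnRd[refRd]; ruleId[refRd] <- "referee_coverage"
  refSv <- conflict & referee == clsSv & referee != clsRd
  cnMeta[refSv] <- cnSv[refSv]; ruleId[refSv] <- "referee_hybrid"
  noRef <- conflict & referee == "none"
  cnMeta[noRef] <- P[noRef]; ruleId[noRef] <- "conflict_no_referee"
  mism <- conflict & referee != "none" & referee != clsRd & referee != clsSv
  cnMeta[mism] <- P[mism]; ruleId[mism] <- "referee_mismatch"

  data.frame(cnMeta = cnMeta, ruleId = ruleId, stringsAsFactors = FALSE)
}

#' Per-bin disagreement error score
#'
#' The squared difference between the two primary callers' harmonised copy
#' numbers on a bin.  Where the coverage caller made no prediction its CN is
#' taken as 0 (it calls gap-free, so a gap means no signal); where the hybrid
#' caller made none, the ploidy is used.
#'
#' @param cnRd coverage caller CN (\code{NA} = absent).
#' @param cnSv hybrid caller CN (\code{NA} = absent).
#' @param P ploidy (scalar or per-bin vector).
#' @return numeric vector of non-negative scores.
#' @examples
#' errorScore(1, 3)            # 4
#' errorScore(NA, 2, P = 2)    # (0 - 2)^2 = 4
#' @export
errorScore <- function(cnRd, cnSv, P = 2) {
  n <- max(length(cnRd), length(cnSv))
  cnRd <- rep_len(cnRd, n); cnSv <- rep_len(cnSv, n); P <- rep_len(P, n)
  cnRd[is.na(cnRd)] <- 0
  cnSv[is.na(cnSv)] <- P[is.na(cnSv)]
  (cnRd - cnSv)^2
}

#' Merge decided bins into consensus segments
#'
#' Maximal runs of contiguous bins (same chromosome, no gap) whose consensus
#' copy numbers agree after rounding to one decimal (half away from zero) are
#' merged.  The merged copy number and error score are bin-length-weighted
#' means; the reported rule id is the one covering the most bases of the
#' segment.
#'
#' @param bins GRanges of decided bins with metadata columns \code{cnMeta},
#'   \code{errorScore} and \code{ruleId}, sorted and non-overlapping.
#' @return GRanges of consensus segments with metadata columns \code{cnMeta},
#'   \code{cnMetaRounded}, \code{errorScore} and \code{ruleId}.
#' @examples
#' b <- GenomicRanges::GRanges("1", IRanges::IRanges(c(1, 101), c(100, 400)),
#'                             cnMeta = c(2.04, 2.01),
#'                             errorScore = c(0, 4), ruleId = "agree_normal")
#' mergeSegments(b)
#' @export
mergeSegments <- function(bins) {
  if (!length(bins)) return(bins)
  stopifnot(all(c("cnMeta", "errorScore", "ruleId") %in%
                colnames(S4Vectors::mcols(bins))))
  bins <- sortByCoord(bins)
  assertDisjoint(bins, "bin set")
  chrom <- as.character(GenomicRanges::seqnames(bins))
  rounded <- roundHalfAway(S4Vectors::mcols(bins)$cnMeta)
  n <- length(bins)
  newRun <- c(TRUE, chrom[-1L] != chrom[-n] |
                    GenomicRanges::start(bins)[-1L] !=
                      GenomicRanges::end(bins)[-n] + 1L |
                    rounded[-1L] != rounded[-n])
  run <- cumsum(newRun)
  w <- GenomicRanges::width(bins)
  cn <- S4Vectors::mcols(bins)$cnMeta
  e <- S4Vectors::mcols(bins)$errorScore
  rid <- S4Vectors::mcols(bins)$ruleId
  segStart <- tapply(GenomicRanges::start(bins), run, min)
  segEnd <- tapply(GenomicRanges::end(bins), run, max)
  segChrom <- tapply(chrom, run, `[`, 1L)
  segCN <- tapply(seq_len(n), run, function(i) sum(cn[i] * w[i]) / sum(w[i]))
  segE <- tapply(seq_len(n), run, function(i) sum(e[i] * w[i]) / sum(w[i]))
  segRule <- tapply(seq_len(n), run, function(i) {
    tw <- tapply(w[i], rid[i], sum)
    names(tw)[which.max(tw)]
  })
  out <- GenomicRanges::GRanges(as.character(segChrom),
                                IRanges::IRanges(as.integer(segStart),
                                                 as.integer(segEnd)))
  S4Vectors::mcols(out)$cnMeta <- as.numeric(segCN)
  S4Vectors::mcols(out)$cnMetaRounded <- roundHalfAway(as.numeric(segCN))
  S4Vectors::mcols(out)$errorScore <- as.numeric(segE)
  S4Vectors::mcols(out)$ruleId <- as.character(segRule)
  sortByCoord(out)
}

## Validator for a consensus segment set (used by the writer and tests).
validateConsensus <- function(segments) {
  stopifnot(is(segments, "GRanges"))
  if (!all(c("cnMeta", "errorScore", "ruleId") %in%
           colnames(S4Vectors::mcols(segments))))
    stop("consensus segments need cnMeta, errorScore and ruleId columns")
  if (any(S4Vectors::mcols(segments)$errorScore < 0))
    stop("error scores must be non-negative")
  if (any(S4Vectors::mcols(segments)$cnMeta < 0))
    stop("consensus copy numbers must be non-negative")
  assertDisjoint(segments, "consensus segment set")
  invisible(TRUE)
}

#' Call a consensus copy-number profile
#'
#' Runs the full pipeline: harmonises the coverage track (bias
#' normalisation) and the hybrid track (log2 conversion or null-ratio
#' equalisation, chosen by the track's value scale), estimates the T1/T2
#' thresholds from the normalised coverage track (unless fixed in the
#' config), partitions the genome on the union of all callers' breakpoints,
#' decides every bin with the consensus rule table and referee arbitration,
#' attaches the per-bin disagreement error score, and merges bins with equal
#' one-decimal copy number into segments.  Deterministic for fixed inputs
#' and config; chromosomes are merged independently (segments never span
#' chromosomes).
#'
#' @param coverage a coverage \linkS4class{CallerTrack} (required).
#' @param hybrid optional hybrid \linkS4class{CallerTrack}.
#' @param referee optional referee \linkS4class{CallerTrack}.
#' @param ploidyModel a \linkS4class{PloidyModel}.
#' @param config a \code{\link{consensusConfig}}.
#' @return GRanges of consensus segments (columns \code{cnMeta},
#'   \code{cnMetaRounded}, \code{errorScore}, \code{ruleId}); the estimated
#'   bias, thresholds and per-rule bin counts are stored in
#'   \code{S4Vectors::metadata()}.
#' @examples
#' cov <- CallerTrack("1", seq(1, 901, 100), seq(100, 1000, 100),
#'                    rep(2, 10), "coverage", "absolute_cn")
#' segs <- callConsensus(cov, config = consensusConfig(
#'   bias = 0, thresholds = Thresholds(2.15)))
#' @export
callConsensus <- function(coverage, hybrid = NULL, referee = NULL,
                          ploidyModel = PloidyModel(),
                          config = consensusConfig()) {
  stopifnot(is(coverage, "CallerTrack"))
  P <- as.numeric(ploidyModel@defaultPloidy)

  bias <- if (is.null(config$bias))
    estimateBias(coverage, P, config$histogramBinWidth)$bias else config$bias
  covH <- harmonizeTrack(coverage, P,
                         consensusConfig(histogramBinWidth = config$histogramBinWidth,
                                         clampLimit = config$clampLimit,
                                         bias = bias))
  thresholds <- if (is.null(config$thresholds))
    computeThresholds(covH, P, config$histogramBinWidth,
                      config$t2SearchInterval) else config$thresholds
  tracks <- list(rd = covH)
  if (!is.null(hybrid)) tracks$sv <- harmonizeTrack(hybrid, P, config)
  if (!is.null(referee)) tracks$ref <- referee

  bins <- unionBreakpoints(tracks)
  chrom <- as.character(GenomicRanges::seqnames(bins))
  Pbin <- suppressWarnings(ploidyAt(ploidyModel, chrom))
  cnRd <- S4Vectors::mcols(bins)$rd
  cnSv <- if (!is.null(hybrid)) S4Vectors::mcols(bins)$sv
          else rep(NA_real_, length(bins))
  refCls <- if (!is.null(referee)) {
    refereeClass(S4Vectors::mcols(bins)$ref, Pbin,
                 if ("ref_class" %in% colnames(S4Vectors::mcols(bins)))
                   S4Vectors::mcols(bins)$ref_class else NULL)
  } else rep("none", length(bins))

  dec <- decideBin(cnRd, cnSv, refCls, thresholds, Pbin)
  decided <- GenomicRanges::granges(bins)
  S4Vectors::mcols(decided)$cnMeta <- dec$cnMeta
  S4Vectors::mcols(decided)$errorScore <- errorScore(cnRd, cnSv, Pbin)
  S4Vectors::mcols(decided)$ruleId <- dec$ruleId

  segs <- mergeSegments(decided)
  validateConsensus(segs)
  S4Vectors::metadata(segs) <- list(
    bias = bias,
    thresholds = thresholds,
    ruleCounts = table(dec$ruleId))
  segs
}
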