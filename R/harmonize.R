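#' Pipeline configuration
#'
#' Collects the tunable parameters of harmonisation and consensus calling.
#'
#' @param histogramBinWidth bin width (CN units) of the length-weighted value
#'   histogram used for bias-peak and threshold-minimum detection.
#' @param clampLimit maximum absolute applied bias correction (CN units).
#' @param equalizerBaseDivisor,equalizerExponentCoefficient parameters of the
#'   equalizer factor \code{q = (1 + cn/base)^(coef * cn)} that undoes the
#'   null-ratio distortion.
#' @param t2SearchInterval numeric length-2: the CN interval searched for the
#'   local frequency minimum defining T2.
#' @param bias optional fixed bias (CN units); \code{NULL} estimates it from
#'   the coverage track.
#' @param thresholds optional fixed \linkS4class{Thresholds}; \code{NULL}
#'   estimates them from the normalised coverage track.
#' @return a named list with class \code{"consensusConfig"}.
#' @examples
#' consensusConfig()
#' @export
consensusConfig <- function(histogramBinWidth = 0.05,
                            clampLimit = 0.5,
                            equalizerBaseDivisor = 100,
                            equalizerExponentCoefficient = 0.75,
                            t2SearchInterval = c(2, 2.3),
                            bias = NULL,
                            thresholds = NULL) {
  stopifnot(histogramBinWidth > 0, clampLimit >= 0,
            equalizerBaseDivisor > 0, equalizerExponentCoefficient >= 0,
            length(t2SearchInterval) == 2L,
            t2SearchInterval[1] < t2SearchInterval[2])
  structure(list(histogramBinWidth = histogramBinWidth,
                 clampLimit = clampLimit,
                 equalizerBaseDivisor = equalizerBaseDivisor,
                 equalizerExponentCoefficient = equalizerExponentCoefficient,
                 t2SearchInterval = t2SearchInterval,
                 bias = bias,
                 thresholds = thresholds),
            class = "consensusConfig")
}

#' Estimate the systematic bias of a coverage caller
#'
#' Coverage callers exhibit a systematic shift of their predicted copy
#' numbers visible as a displacement of the frequency peak from the ploidy.
#' The bias is the difference between the ploidy and the CN at the frequency
#' peak.  The histogram is length-weighted (long intervals carry more mass)
#' with bins centred on multiples of \code{binWidth}; among local maxima the
#' peak nearest the ploidy is used (ties: higher frequency, then smaller CN).
#'
#' @param track a coverage \linkS4class{CallerTrack} on the absolute CN
#'   scale.
#' @param P ploidy anchoring the peak search.
#' @param binWidth histogram bin width in CN units.
#' @return a list with elements \code{bias} (\code{P - peak_cn}),
#'   \code{peakCN} and \code{binWidth}.
#' @examples
#' tr <- CallerTrack("1", c(1, 101), c(100, 200), c(1.9, 1.9),
#'                   "coverage", "absolute_cn")
#' estimateBias(tr, P = 2)$bias
#' @export
estimateBias <- function(track, P = 2, binWidth = 0.05) {
  stopifnot(is(track, "CallerTrack"))
  if (track@valueScale != "absolute_cn")
    stop("bias estimation requires an absolute_cn track")
  gr <- track@calls
  if (!length(gr)) stop("cannot estimate bias from an empty track")
  h <- weightedHistogram(S4Vectors::mcols(gr)$value,
                         GenomicRanges::width(gr), binWidth)
  if (length(h$freq) > 1L && length(unique(h$freq)) == 1L) {
    warning("flat copy-number histogram; assuming bias 0")
    return(list(bias = 0, peakCN = P, binWidth = binWidth))
  }
  n <- length(h$freq)
  left  <- c(0, h$freq[-n])
  right <- c(h$freq[-1L], 0)
  isMax <- h$freq >= left & h$freq >= right & h$freq > 0
  cand <- which(isMax)
  ## nearest ploidy, then highest frequency, then smaller CN
  d <- abs(h$center[cand] - P)
  cand <- cand[order(d, -h$freq[cand], h$center[cand])]
  peak <- h$center[cand[1L]]
  list(bias = P - peak, peakCN = peak, binWidth = binWidth)
}

#' Copy-number-dependent bias normalisation
#'
#' Applies \code{CN_norm = CN + factor * bias} with the linear factor
#' \code{factor = min(CN / 2, 1)}, so small copy numbers (which show less
#' bias) are corrected less.  The applied correction is clamped to
#' \code{clampLimit} (0.5 CN units by default) in absolute value, and the
#' result is floored at 0.
#'
#' @param cn numeric vector of absolute copy numbers (>= 0).
#' @param bias estimated bias in CN units (see \code{\link{estimateBias}}).
#' @param clampLimit maximum absolute applied correction.
#' @return numeric vector of normalised copy numbers.
#' @examples
#' normalizeCN(1.9, bias = 0.1)   # factor 0.95 -> 1.995
#' normalizeCN(4.0, bias = 0.8)   # correction clamped to +0.5 -> 4.5
#' @export
normalizeCN <- function(cn, bias, clampLimit = 0.5) {
  stopifnot(all(cn >= 0))
  corr <- pmin(pmax(pmin(cn / 2, 1) * bias, -clampLimit), clampLimit)
  out <- pmax(cn + corr, 0)
  ## double rounding of cn + corr can push the realised correction a few ulp
  ## past the clamp; pull it back so |out - cn| <= clampLimit holds exactly
  for (i in 1:5) {
    d <- out - cn
    high <- d > clampLimit
    low <- d < -clampLimit & out > 0
    if (!any(high) && !any(low)) break
    ## twice the excess: a single ulp of excess is a rounding tie that
    ## subtracting the excess alone cannot cross
    out[high] <- out[high] - 2 * (d[high] - clampLimit)
    out[low] <- pmax(out[low] - 2 * (d[low] + clampLimit), 0)
  }
  out
}

#' Convert log2 ratios to absolute copy numbers
#'
#' Log2 ratios against a matched sample are first centred by subtracting the
#' genome-wide (length-weighted) median, then mapped to the absolute scale as
#' \code{P * 2^corrected}.  The centring forces the genome-wide median of the
#' output onto the ploidy.
#'
#' @param values numeric vector of log2 ratios, one per bin.
#' @param P ploidy.
#' @param weights optional bin lengths used for the weighted median; equal
#'   weights by default.
#' @return numeric vector of absolute copy numbers.
#' @examples
#' log2ToAbsolute(c(0, 0, 1), P = 2)   # median 0 background; 1 -> CN 4
#' @export
log2ToAbsolute <- function(values, P = 2, weights = NULL) {
  if (!length(values)) stop("no log2 values to convert")
  if (is.null(weights)) weights <- rep(1, length(values))
  med <- weightedMedian(values, weights)
  P * 2^(values - med)
}

#' Equalize ratios measured against a null alignment
#'
#' Values reported relative to a zero-coverage null alignment are
#' non-negative but distorted: the distortion grows exponentially with the
#' true amplification.  The equalizer factor
#' \code{q = (1 + cn/base)^(coef * cn)} (base 100, coefficient 0.75) undoes
#' it: \code{CN = cn * q(cn)}.  The correction is the identity at 0 and
#' strictly increasing.
#'
#' @param cn numeric vector of non-negative null-ratio values.
#' @param baseDivisor,exponentCoefficient equalizer parameters.
#' @return numeric vector of absolute copy numbers.
#' @examples
#' equalizeNullRatio(4)   # 4 * 1.04^3 = 4.499456
#' @export
equalizeNullRatio <- function(cn, baseDivisor = 100,
                              exponentCoefficient = 0.75) {
  if (any(cn < 0)) stop("null-ratio values must be non-negative")
  cn * (1 + cn / baseDivisor)^(exponentCoefficient * cn)
}

## Inverse of the equalizer map y -> y * q(y); scalar root-finding on the
## unique values only (the map is strictly increasing and >= identity).
invertEqualizer <- function(target, baseDivisor = 100,
                            exponentCoefficient = 0.75, tol = 1e-12) {
  stopifnot(all(target >= 0))
  uniq <- unique(target)
  inv <- vapply(uniq, function(tt) {
    if (tt == 0) return(0)
    stats::uniroot(function(y)
      equalizeNullRatio(y, baseDivisor, exponentCoefficient) - tt,
      lower = 0, upper = tt, tol = tol)$root
  }, numeric(1))
  inv[match(target, uniq)]
}

#' Estimate the consensus thresholds T1 / T2
#'
#' T2 is the CN at the local minimum of the (length-weighted) copy-number
#' frequency histogram of the normalised coverage track inside the search
#' interval (default [2, 2.3]); T1 is derived as \code{2 * P - T2}.  A local
#' minimum is a histogram bin strictly lower than both neighbours whose
#' centre lies inside the interval; among several, the lowest-frequency one
#' wins, ties going to the smaller CN.  If no interior local minimum exists
#' the midpoint of the search interval is used with a warning.
#'
#' @param track a normalised coverage \linkS4class{CallerTrack}.
#' @param P ploidy.
#' @param binWidth histogram bin width in CN units.
#' @param searchInterval numeric length-2 CN interval to scan.
#' @return a \linkS4class{Thresholds}.
#' @examples
#' tr <- CallerTrack("1", seq(1, 901, 100), seq(100, 1000, 100),
#'                   c(2, 2, 2, 2, 2.1, 2.3, 2.3, 2.3, 3, 3),
#'                   "coverage", "absolute_cn")
#' computeThresholds(tr, P = 2)
#' @export
computeThresholds <- function(track, P = 2, binWidth = 0.05,
                              searchInterval = c(2, 2.3)) {
  stopifnot(is(track, "CallerTrack"), length(track@calls) > 0)
  h <- weightedHistogram(S4Vectors::mcols(track@calls)$value,
                         GenomicRanges::width(track@calls), binWidth)
  n <- length(h$freq)
  fallback <- mean(searchInterval)
  t2 <- NA_real_
  if (n >= 3L) {
    interior <- seq(2L, n - 1L)
    isMin <- h$freq[interior] < h$freq[interior - 1L] &
             h$freq[interior] < h$freq[interior + 1L]
    inWindow <- h$center[interior] >= searchInterval[1] &
                h$center[interior] <= searchInterval[2]
    cand <- interior[isMin & inWindow]
    if (length(cand)) {
      cand <- cand[order(h$freq[cand], h$center[cand])]
      t2 <- h$center[cand[1L]]
    }
  }
  if (is.na(t2)) {
    warning(sprintf("no interior local minimum in [%g, %g]; falling back to T2 = %g",
                    searchInterval[1], searchInterval[2], fallback))
    t2 <- fallback
  }
  Thresholds(t2, ploidy = P)
}

#' Harmonise a caller track onto the absolute copy-number scale
#'
#' Coverage tracks are bias-normalised (\code{\link{estimateBias}} +
#' \code{\link{normalizeCN}}); hybrid tracks are converted with
#' \code{\link{log2ToAbsolute}} (matched-sample mode) or
#' \code{\link{equalizeNullRatio}} (null-alignment mode); referee tracks are
#' returned unchanged, as their magnitudes are never used.
#'
#' @param track a \linkS4class{CallerTrack}.
#' @param P ploidy.
#' @param config a \code{\link{consensusConfig}}.
#' @return a \linkS4class{CallerTrack} on the \code{absolute_cn} scale
#'   (referee tracks unchanged).
#' @export
harmonizeTrack <- function(track, P = 2, config = consensusConfig()) {
  gr <- track@calls
  v <- S4Vectors::mcols(gr)$value
  switch(track@callerRole,
    coverage = {
      b <- if (is.null(config$bias))
        estimateBias(track, P, config$histogramBinWidth)$bias
      else config$bias
      S4Vectors::mcols(gr)$value <- normalizeCN(v, b, config$clampLimit)
      trackFromGRanges(gr, "coverage", "absolute_cn")
    },
    hybrid = {
      if (track@valueScale == "log2_vs_matched") {
        S4Vectors::mcols(gr)$value <-
          log2ToAbsolute(v, P, GenomicRanges::width(gr))
      } else {
        S4Vectors::mcols(gr)$value <-
          equalizeNullRatio(v, config$equalizerBaseDivisor,
                            config$equalizerExponentCoefficient)
      }
      trackFromGRanges(gr, "hybrid", "absolute_cn")
    },
    referee = track)
}
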