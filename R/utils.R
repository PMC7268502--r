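## Internal numeric / coordinate helpers shared across modules.

#' Normalise chromosome names to the canonical token set
#'
#' Caller outputs disagree on the "chr" prefix; internally chromosomes are
#' stored without it ("chr1" and "1" both become "1").
#'
#' @param x character vector of chromosome names.
#' @return character vector of canonical tokens.
#' @examples
#' normalizeChrom(c("chr1", "1", "chrX"))
#' @export
normalizeChrom <- function(x) {
  x <- as.character(x)
  sub("^chr", "", x)
}

#' Round to one decimal, half away from zero
#'
#' The merge criterion for consensus bins is equality of copy numbers rounded
#' to one decimal.  Base \code{round()} rounds half to even, which is
#' locale-stable but surprises at the x.x5 boundaries, so the merge uses
#' half-away-from-zero.  Values within 1e-9 of a .x5 boundary are treated as
#' lying on it (doubles cannot represent most decimal literals exactly).
#'
#' @param x numeric vector.
#' @return numeric vector rounded to one decimal place.
#' @examples
#' roundHalfAway(c(2.05, 2.04, -2.05))
#' @export
roundHalfAway <- function(x) {
  sign(x) * floor(abs(x) * 10 + 0.5 + 1e-9) / 10
}

## Weighted median (lower median: smallest value whose cumulative weight
## reaches half the total).  Used for the genome-wide median of log2 values,
## weighted by bin length.
weightedMedian <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0), any(w > 0))
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w)
  x[which(cw >= sum(w) / 2)[1L]]
}

## Length-weighted value histogram on a grid of bins centred at integer
## multiples of `binWidth`.  Returns a contiguous grid (zero-filled) so that
## local-extremum scans see empty bins.
weightedHistogram <- function(values, weights, binWidth) {
  stopifnot(binWidth > 0, length(values) == length(weights))
  idx <- as.integer(round(values / binWidth))
  grid <- seq(min(idx), max(idx))
  freq <- vapply(grid, function(i) sum(weights[idx == i]), numeric(1))
  list(center = grid * binWidth, freq = freq)
}

## Sort a GRanges by (chromosome token, start) without relying on seqlevel
## order; returns the GRanges reordered.
sortByCoord <- function(gr) {
  gr[order(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr))]
}

## Assert that a GRanges has no within-chromosome overlaps; strand ignored.
assertDisjoint <- function(gr, what = "track") {
  if (length(gr) < 2L) return(invisible(TRUE))
  gr <- sortByCoord(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  same <- chrom[-1L] == chrom[-length(gr)]
  hit <- which(same & GenomicRanges::start(gr)[-1L] <= GenomicRanges::end(gr)[-length(gr)])
  if (length(hit)) {
    stop(sprintf("%s has overlapping intervals, first at %s:%d-%d / %s:%d-%d",
                 what,
                 chrom[hit[1L]], GenomicRanges::start(gr)[hit[1L]],
                 GenomicRanges::end(gr)[hit[1L]],
                 chrom[hit[1L] + 1L], GenomicRanges::start(gr)[hit[1L] + 1L],
                 GenomicRanges::end(gr)[hit[1L] + 1L]))
  }
  invisible(TRUE)
}

## Put two GRanges (or a list of them) on the union of their seqlevels so
## that findOverlaps / c() do not warn about disjoint sequence universes.
alignSeqlevels <- function(...) {
  grs <- list(...)
  if (length(grs) == 1L && is.list(grs[[1L]])) grs <- grs[[1L]]
  lev <- unique(unlist(lapply(grs, GenomeInfoDb::seqlevels)))
  lapply(grs, function(g) {
    GenomeInfoDb::seqlevels(g) <- lev
    g
  })
}

## Concatenate a list of GRanges with harmonised seqlevels.
bindGR <- function(grl) {
  do.call(c, alignSeqlevels(grl))
}

## Build a GRanges from canonical tokens and 1-based closed coordinates.
makeGR <- function(chrom, start, end) {
  GenomicRanges::GRanges(normalizeChrom(chrom),
                         IRanges::IRanges(start = start, end = end))
}
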