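#' Construct a CallerTrack
#'
#' Builds a validated \linkS4class{CallerTrack} from parallel coordinate
#' vectors.  Coordinates are 1-based closed (the GRanges convention);
#' chromosome names are normalised to the canonical token set (any "chr"
#' prefix is stripped).  Calls are sorted on construction; overlapping
#' intervals are rejected.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 1-based closed.
#' @param value numeric vector of per-interval values on \code{valueScale}.
#'   \code{NA} is allowed only for referee calls with an \code{svClass}.
#' @param callerRole \code{"coverage"}, \code{"hybrid"} or \code{"referee"}.
#' @param valueScale \code{"absolute_cn"}, \code{"log2_vs_matched"} or
#'   \code{"ratio_vs_null"}.
#' @param svClass optional character vector of referee class labels
#'   (\code{"deletion"} / \code{"amplification"}, \code{NA} where a numeric
#'   value is given).
#' @return a \linkS4class{CallerTrack}.
#' @examples
#' CallerTrack(chrom = c("1", "1"), start = c(1, 101), end = c(100, 200),
#'             value = c(2, 4), callerRole = "coverage",
#'             valueScale = "absolute_cn")
#' @export
CallerTrack <- function(chrom, start, end, value,
                        callerRole = c("coverage", "hybrid", "referee"),
                        valueScale = c("absolute_cn", "log2_vs_matched",
                                       "ratio_vs_null"),
                        svClass = NULL) {
  callerRole <- match.arg(callerRole)
  valueScale <- match.arg(valueScale)
  gr <- makeGR(chrom, start, end)
  S4Vectors::mcols(gr)$value <- as.numeric(value)
  if (!is.null(svClass)) S4Vectors::mcols(gr)$svClass <- as.character(svClass)
  gr <- sortByCoord(gr)
  new("CallerTrack", calls = gr, callerRole = callerRole,
      valueScale = valueScale)
}

## Rebuild a track around a transformed GRanges, keeping role/scale explicit.
trackFromGRanges <- function(gr, callerRole, valueScale) {
  new("CallerTrack", calls = sortByCoord(gr), callerRole = callerRole,
      valueScale = valueScale)
}

#' Accessors for CallerTrack
#'
#' \code{calls()} returns the underlying GRanges (with the \code{value}
#' metadata column), \code{callerRole()} and \code{valueScale()} the role and
#' scale tags.
#'
#' @param x a \linkS4class{CallerTrack}.
#' @return \code{calls()}: a GRanges; the others: a character scalar.
#' @name CallerTrack-accessors
#' @aliases calls callerRole valueScale
#' @examples
#' tr <- CallerTrack("1", 1, 100, 2, "coverage", "absolute_cn")
#' calls(tr)
#' callerRole(tr)
NULL

#' @rdname CallerTrack-accessors
#' @export
setMethod("calls", "CallerTrack", function(x) x@calls)

#' @rdname CallerTrack-accessors
#' @export
setMethod("callerRole", "CallerTrack", function(x) x@callerRole)

#' @rdname CallerTrack-accessors
#' @export
setMethod("valueScale", "CallerTrack", function(x) x@valueScale)

#' @describeIn CallerTrack-accessors number of calls in the track.
#' @export
setMethod("length", "CallerTrack", function(x) length(x@calls))

setMethod("show", "CallerTrack", function(object) {
  cat(sprintf("CallerTrack: %s caller, %d call(s) on %d chromosome(s), scale %s\n",
              object@callerRole, length(object@calls),
              length(unique(as.character(GenomicRanges::seqnames(object@calls)))),
              object@valueScale))
  if (length(object@calls)) {
    v <- S4Vectors::mcols(object@calls)$value
    cat(sprintf("  value range: [%g, %g]%s\n",
                suppressWarnings(min(v, na.rm = TRUE)),
                suppressWarnings(max(v, na.rm = TRUE)),
                if (anyNA(v)) " (class-only calls present)" else ""))
  }
  invisible(NULL)
})
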