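#' CallerTrack: one caller's CNV predictions
#'
#' Ordered, non-overlapping genomic intervals with one value per interval,
#' plus the caller's role and the scale its values live on.  Roles:
#' \describe{
#'   \item{coverage}{gap-free read-depth caller reporting absolute copy
#'     numbers (\code{value_scale = "absolute_cn"}).}
#'   \item{hybrid}{coverage + read-pair caller reporting either log2 ratios
#'     against a matched sample (\code{"log2_vs_matched"}) or non-negative
#'     ratios against a zero-coverage null alignment
#'     (\code{"ratio_vs_null"}).}
#'   \item{referee}{a caller whose deletion/amplification direction is
#'     trusted but whose magnitudes are not; used only to arbitrate
#'     conflicts.  Calls may carry a class label instead of a value.}
#' }
#' Intervals are stored as a \link[GenomicRanges]{GRanges} (1-based closed)
#' with metadata columns \code{value} (numeric; \code{NA} allowed only for
#' referee calls that carry \code{svClass}) and, for referee tracks,
#' \code{svClass} (\code{"deletion"}, \code{"amplification"} or \code{NA}).
#'
#' @slot calls GRanges of the caller's intervals, sorted, non-overlapping.
#' @slot callerRole one of \code{"coverage"}, \code{"hybrid"},
#'   \code{"referee"}.
#' @slot valueScale one of \code{"absolute_cn"}, \code{"log2_vs_matched"},
#'   \code{"ratio_vs_null"}.
#' @seealso \code{\link{CallerTrack}} for the constructor,
#'   \code{\link{callConsensus}}.
#' @export
setClass("CallerTrack",
         representation(calls = "GRanges",
                        callerRole = "character",
                        valueScale = "character"))

.validCallerTrack <- function(object) {
  msg <- character()
  roles <- c("coverage", "hybrid", "referee")
  scales <- c("absolute_cn", "log2_vs_matched", "ratio_vs_null")
  if (!(length(object@callerRole) == 1L && object@callerRole %in% roles))
    msg <- c(msg, sprintf("callerRole must be one of %s",
                          paste(roles, collapse = ", ")))
  if (!(length(object@valueScale) == 1L && object@valueScale %in% scales))
    msg <- c(msg, sprintf("valueScale must be one of %s",
                          paste(scales, collapse = ", ")))
  if (!length(msg)) {
    if (object@callerRole == "coverage" && object@valueScale != "absolute_cn")
      msg <- c(msg, "a coverage track must be on the absolute_cn scale")
  }
  gr <- object@calls
  if (!"value" %in% colnames(S4Vectors::mcols(gr)))
    return(c(msg, "calls must carry a 'value' metadata column"))
  v <- S4Vectors::mcols(gr)$value
  if (!is.numeric(v))
    msg <- c(msg, "'value' must be numeric")
  hasClass <- if ("svClass" %in% colnames(S4Vectors::mcols(gr)))
    !is.na(S4Vectors::mcols(gr)$svClass) else rep(FALSE, length(gr))
  bad <- !is.finite(v) & !(is.na(v) & hasClass)
  if (any(bad))
    msg <- c(msg, "values must be finite (NA only for class-only referee calls)")
  if (object@valueScale == "ratio_vs_null" && any(v < 0, na.rm = TRUE))
    msg <- c(msg, "ratio_vs_null values are ratios relative to zero coverage and must be non-negative")
  if (length(gr)) {
    if (any(GenomicRanges::start(gr) < 1L))
      msg <- c(msg, "interval starts must be >= 1 (1-based closed storage)")
    chrom <- as.character(GenomicRanges::seqnames(gr))
    o <- order(chrom, GenomicRanges::start(gr))
    if (!identical(o, seq_along(gr)))
      msg <- c(msg, "calls must be sorted by chromosome and start")
    ok <- tryCatch(assertDisjoint(gr, "CallerTrack"), error = function(e) e)
    if (inherits(ok, "error")) msg <- c(msg, conditionMessage(ok))
  }
  if (length(msg)) msg else TRUE
}
setValidity("CallerTrack", .validCallerTrack)

#' PloidyModel: expected copy count per chromosome
#'
#' Autosomes have the default ploidy (2 in the standard diploid model); the
#' allosomes (X, Y) get 2 in a female model and 1 in a male model.  With
#' \code{sex = "unspecified"} the allosomes fall back to the default ploidy.
#' A per-chromosome lookup can override any token (e.g. haploid organisms,
#' chrM).  Unrecognised tokens without an override fall back to the default
#' ploidy with a warning.
#'
#' @slot defaultPloidy positive integer ploidy for autosomes.
#' @slot sex \code{"female"}, \code{"male"} or \code{"unspecified"}.
#' @slot lookup named numeric vector of per-chromosome overrides (canonical
#'   tokens, no "chr" prefix).
#' @seealso \code{\link{PloidyModel}}, \code{\link{ploidyAt}}
#' @export
setClass("PloidyModel",
         representation(defaultPloidy = "integer",
                        sex = "character",
                        lookup = "numeric"))

setValidity("PloidyModel", function(object) {
  msg <- character()
  if (!(length(object@defaultPloidy) == 1L && object@defaultPloidy >= 1L))
    msg <- c(msg, "defaultPloidy must be a positive integer")
  if (!(length(object@sex) == 1L &&
        object@sex %in% c("female", "male", "unspecified")))
    msg <- c(msg, "sex must be female, male or unspecified")
  if (length(object@lookup) && is.null(names(object@lookup)))
    msg <- c(msg, "lookup must be a named vector")
  if (length(msg)) msg else TRUE
})

#' Thresholds: the deletion / normal / amplification boundaries
#'
#' Copy numbers below \code{T1} are deletions, above \code{T2}
#' amplifications, in between normal.  \code{T2} is estimated as the local
#' minimum of the coverage caller's CN frequency histogram inside the search
#' interval (default [2, 2.3] for ploidy 2) and \code{T1 = 2 P - T2}, so the
#' two are symmetric about the ploidy.
#'
#' @slot t1 lower boundary (CN units).
#' @slot t2 upper boundary (CN units).
#' @slot ploidy the ploidy the thresholds were derived for.
#' @seealso \code{\link{computeThresholds}}, \code{\link{classifyCN}}
#' @export
setClass("Thresholds",
         representation(t1 = "numeric", t2 = "numeric", ploidy = "numeric"))

setValidity("Thresholds", function(object) {
  msg <- character()
  if (abs(object@t1 - (2 * object@ploidy - object@t2)) > 1e-9)
    msg <- c(msg, "t1 must equal 2 * ploidy - t2")
  if (object@ploidy == 2 && (object@t2 < 2 || object@t2 > 2.3))
    msg <- c(msg, "for ploidy 2, t2 must lie in [2, 2.3]")
  if (length(msg)) msg else TRUE
})

#' MetricsReport: gene-level accuracy of a CN prediction
#'
#' Holds the five benchmark metrics (mean squared error, mean absolute
#' error, mean log ratio error, residual variance around each unique true CN,
#' micro-averaged Matthews correlation coefficient) plus the micro-summed
#' confusion counts over the three classes deletion / normal / amplification.
#'
#' @slot mse,mae,mlre,residualVariance,mcc numeric scalar metrics.
#' @slot confusion named numeric vector (TP, TN, FP, FN) summed over classes.
#' @slot nGenes number of gene pairs evaluated.
#' @slot nTrueCNLevels number of unique (integer-rounded) true CN levels.
#' @slot missingGenes ids present in the truth table but absent from the
#'   gene set (reported, never silently dropped).
#' @seealso \code{\link{evaluateCalls}}
#' @export
setClass("MetricsReport",
         representation(mse = "numeric", mae = "numeric", mlre = "numeric",
                        residualVariance = "numeric", mcc = "numeric",
                        confusion = "numeric", nGenes = "integer",
                        nTrueCNLevels = "integer",
                        missingGenes = "character"))

#' SyntheticScenario: a ground-truthed simulated calling problem
#'
#' The truth profile, the three emulated caller tracks derived from it, the
#' generated gene set with its truth table, and the seed that produced them.
#'
#' @slot seed integer RNG seed.
#' @slot truth GRanges of CNV segments with metadata column \code{trueCN}
#'   (background between segments is at ploidy).
#' @slot coverage,hybrid,referee the emulated \linkS4class{CallerTrack}s.
#' @slot genes GRanges with metadata column \code{gene_id}.
#' @slot truthTable data.frame with columns \code{gene_id}, \code{true_cn}.
#' @seealso \code{\link{simulateScenario}}
#' @export
setClass("SyntheticScenario",
         representation(seed = "integer", truth = "GRanges",
                        coverage = "CallerTrack", hybrid = "CallerTrack",
                        referee = "CallerTrack", genes = "GRanges",
                        truthTable = "data.frame"))
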