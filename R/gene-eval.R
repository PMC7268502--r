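#' Map segment predictions to per-gene copy numbers
#'
#' Each gene's predicted copy number is the length-weighted sum of the copy
#' numbers of the segments overlapping it: a segment covering \code{w} of a
#' \code{L}-bp gene contributes \code{cn * w / L}, and uncovered bases are
#' filled with the chromosome's ploidy (\code{ploidy * gap / L}).  Genes on a
#' chromosome with no segments at all are still handled the same way (fully
#' ploidy-filled); genes whose chromosome token is unrecognised get the
#' default ploidy with a warning.  When \code{evalLength} is provided for a
#' gene (truth derived from a partial segment), the gene is truncated to its
#' first \code{evalLength} bases before mapping.
#'
#' @param segments GRanges with a copy-number metadata column (first of
#'   \code{cnMeta} / \code{value} / \code{cn} found), non-overlapping.
#' @param genes GRanges with metadata column \code{gene_id}.
#' @param ploidyModel a \linkS4class{PloidyModel}.
#' @param evalLength optional numeric vector parallel to \code{genes}
#'   (\code{NA} = use the full gene).
#' @return named numeric vector of predicted copy numbers, one per gene.
#' @examples
#' segs <- GenomicRanges::GRanges("1", IRanges::IRanges(c(1, 601), c(600, 1000)),
#'                                cnMeta = c(2, 4))
#' g <- GenomicRanges::GRanges("1", IRanges::IRanges(1, 1000), gene_id = "g1")
#' mapSegmentsToGenes(segs, g, PloidyModel())   # 0.6*2 + 0.4*4 = 2.8
#' @export
mapSegmentsToGenes <- function(segments, genes, ploidyModel = PloidyModel(),
                               evalLength = NULL) {
  stopifnot(is(segments, "GRanges"), is(genes, "GRanges"),
            "gene_id" %in% colnames(S4Vectors::mcols(genes)))
  assertDisjoint(segments, "segment set")
  cnCol <- intersect(c("cnMeta", "value", "cn"),
                     colnames(S4Vectors::mcols(segments)))
  if (!length(cnCol)) stop("segments carry no copy-number column")
  cn <- S4Vectors::mcols(segments)[[cnCol[1L]]]

  g <- GenomicRanges::granges(genes)
  GenomicRanges::strand(g) <- "*"
  if (!is.null(evalLength)) {
    stopifnot(length(evalLength) == length(g))
    trunc <- !is.na(evalLength) & evalLength < GenomicRanges::width(g)
    GenomicRanges::end(g)[trunc] <-
      GenomicRanges::start(g)[trunc] + as.integer(evalLength[trunc]) - 1L
  }
  chromTok <- as.character(GenomicRanges::seqnames(g))
  known <- chromTok %in% c(.AUTOSOMES, .ALLOSOMES,
                           names(ploidyModel@lookup))
  P <- suppressWarnings(ploidyAt(ploidyModel, chromTok))
  if (any(!known))
    warning(sprintf("gene(s) on unrecognised chromosome(s) %s: predicted CN set to ploidy",
                    paste(unique(chromTok[!known]), collapse = ", ")))

  L <- GenomicRanges::width(g)
  al <- alignSeqlevels(g, segments)
  g <- al[[1L]]; segments <- al[[2L]]
  ov <- GenomicRanges::findOverlaps(g, segments, ignore.strand = TRUE)
  pi <- GenomicRanges::pintersect(g[S4Vectors::queryHits(ov)],
                                  segments[S4Vectors::subjectHits(ov)],
                                  ignore.strand = TRUE)
  w <- GenomicRanges::width(pi)
  contrib <- cn[S4Vectors::subjectHits(ov)] * w
  covered <- tapply(w, S4Vectors::queryHits(ov), sum)
  weighted <- tapply(contrib, S4Vectors::queryHits(ov), sum)
  pred <- P * 1        # fully uncovered genes sit at ploidy
  idx <- as.integer(names(covered))
  pred[idx] <- (weighted + P[idx] * (L[idx] - covered)) / L[idx]
  stats::setNames(as.numeric(pred), S4Vectors::mcols(genes)$gene_id)
}

.checkPairs <- function(trueCN, predCN) {
  if (!length(trueCN)) stop("no gene pairs to evaluate")
  stopifnot(length(trueCN) == length(predCN),
            all(is.finite(trueCN)), all(is.finite(predCN)))
}

#' Mean squared / mean absolute error over gene copy numbers
#'
#' @param trueCN,predCN numeric vectors of true and predicted copy numbers.
#' @return a numeric scalar.
#' @examples
#' mseCN(c(2, 4), c(1, 6))   # 2.5
#' maeCN(c(2, 4), c(1, 6))   # 1.5
#' @export
mseCN <- function(trueCN, predCN) {
  .checkPairs(trueCN, predCN)
  mean((trueCN - predCN)^2)
}

#' @rdname mseCN
#' @export
maeCN <- function(trueCN, predCN) {
  .checkPairs(trueCN, predCN)
  mean(abs(trueCN - predCN))
}

#' Mean log ratio error
#'
#' \code{mean(|ln((x + 1) / (xhat + 1))|)} over genes; the +1 keeps the
#' ratio finite at copy number 0 and damps the outlier penalty of squared
#' errors.
#'
#' @inheritParams mseCN
#' @return a numeric scalar >= 0.
#' @examples
#' mlre(3, 1)   # ln 2
#' @export
mlre <- function(trueCN, predCN) {
  .checkPairs(trueCN, predCN)
  stopifnot(all(trueCN >= 0), all(predCN >= 0))
  mean(abs(log((trueCN + 1) / (predCN + 1))))
}

#' Variance of residuals around each unique true copy number
#'
#' Genes are grouped by their true copy number rounded to the nearest
#' integer; within each group the population variance of the residuals
#' \code{z = x - xhat} is computed (a singleton group contributes 0), and the
#' group variances are averaged over the M groups.  Low values mean the
#' caller's predictions cluster tightly around each true CN level.
#'
#' @inheritParams mseCN
#' @return a numeric scalar >= 0.
#' @examples
#' residualVariance(c(2, 2), c(1, 3))   # residuals {1, -1}: variance 1
#' @export
residualVariance <- function(trueCN, predCN) {
  .checkPairs(trueCN, predCN)
  z <- trueCN - predCN
  grp <- round(trueCN)
  v <- tapply(z, grp, function(zi) mean((zi - mean(zi))^2))
  mean(v)
}

#' Classify a gene copy number as deletion / normal / amplification
#'
#' For ploidy 2 the class boundaries are the conventional 1.75 and 2.75:
#' copy numbers below 1.75 are deletions, above 2.75 amplifications, the
#' boundary values themselves normal.  For other ploidies the boundaries
#' scale proportionally (\code{0.875 * P} and \code{1.375 * P}).
#'
#' @param cn numeric vector of copy numbers.
#' @param P ploidy (scalar or vector).
#' @return character vector over \code{c("deletion", "normal",
#'   "amplification")}.
#' @examples
#' classifyGene(c(0.3, 1.75, 2.8))
#' @export
classifyGene <- function(cn, P = 2) {
  n <- length(cn)
  P <- rep_len(P, n)
  lo <- 0.875 * P
  hi <- 1.375 * P
  out <- rep("normal", n)
  out[cn < lo] <- "deletion"
  out[cn > hi] <- "amplification"
  out
}

#' Micro-averaged Matthews correlation coefficient
#'
#' For each of the three classes a one-vs-rest confusion matrix is built;
#' the TP, TN, FP and FN counts are summed across classes (micro-averaging)
#' and the binary MCC formula is applied to the summed counts.  Robust to
#' the strongly unbalanced deletion/amplification ratios typical of CNV
#' benchmarks.
#'
#' @param trueClass,predClass equal-length character vectors over
#'   \code{c("deletion", "normal", "amplification")}.
#' @return a numeric scalar in [-1, 1]; 0 (with a warning) when a marginal
#'   count is zero and the denominator vanishes.
#' @examples
#' mccMicro(c("deletion", "deletion", "normal", "amplification"),
#'          c("deletion", "normal", "normal", "amplification"))   # 0.625
#' @export
mccMicro <- function(trueClass, predClass) {
  stopifnot(length(trueClass) == length(predClass), length(trueClass) > 0)
  classes <- c("deletion", "normal", "amplification")
  stopifnot(all(trueClass %in% classes), all(predClass %in% classes))
  tp <- tn <- fp <- fn <- 0
  for (cl in classes) {
    t <- trueClass == cl
    p <- predClass == cl
    tp <- tp + sum(t & p)
    tn <- tn + sum(!t & !p)
    fp <- fp + sum(!t & p)
    fn <- fn + sum(t & !p)
  }
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) {
    warning("zero marginal count; MCC undefined, returning 0")
    return(0)
  }
  (tp * tn - fp * fn) / den
}

#' Evaluate a consensus (or single-caller) prediction against a truth table
#'
#' Maps the segments to genes with \code{\link{mapSegmentsToGenes}}, pairs
#' the mapped predictions with the truth table and computes all five metrics
#' plus the micro-summed confusion counts.  Genes present in the truth table
#' but absent from the gene set are reported in the result, never silently
#' dropped.
#'
#' @param segments GRanges of predictions (see
#'   \code{\link{mapSegmentsToGenes}}).
#' @param genes GRanges with metadata column \code{gene_id}.
#' @param truth data.frame with columns \code{gene_id}, \code{true_cn} and
#'   optionally \code{eval_length} (see \code{\link{readTruthTable}}).
#' @param ploidyModel a \linkS4class{PloidyModel}.
#' @return a \linkS4class{MetricsReport}.
#' @export
evaluateCalls <- function(segments, genes, truth,
                          ploidyModel = PloidyModel()) {
  stopifnot(all(c("gene_id", "true_cn") %in% colnames(truth)))
  missing <- setdiff(truth$gene_id, S4Vectors::mcols(genes)$gene_id)
  shared <- intersect(truth$gene_id, S4Vectors::mcols(genes)$gene_id)
  if (!length(shared))
    stop("no gene in the truth table is present in the gene set")
  genes <- genes[match(shared, S4Vectors::mcols(genes)$gene_id)]
  truth <- truth[match(shared, truth$gene_id), , drop = FALSE]
  evalLength <- if ("eval_length" %in% colnames(truth))
    truth$eval_length else NULL
  pred <- mapSegmentsToGenes(segments, genes, ploidyModel, evalLength)
  x <- truth$true_cn
  xhat <- as.numeric(pred)
  P <- suppressWarnings(
    ploidyAt(ploidyModel, as.character(GenomicRanges::seqnames(genes))))
  trueClass <- classifyGene(x, P)
  predClass <- classifyGene(xhat, P)
  classes <- c("deletion", "normal", "amplification")
  conf <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  for (cl in classes) {
    t <- trueClass == cl; p <- predClass == cl
    conf <- conf + c(TP = sum(t & p), TN = sum(!t & !p),
                     FP = sum(!t & p), FN = sum(t & !p))
  }
  new("MetricsReport",
      mse = mseCN(x, xhat), mae = maeCN(x, xhat), mlre = mlre(x, xhat),
      residualVariance = residualVariance(x, xhat),
      mcc = suppressWarnings(mccMicro(trueClass, predClass)),
      confusion = conf, nGenes = length(x),
      nTrueCNLevels = length(unique(round(x))),
      missingGenes = missing)
}

#' Accessors for MetricsReport
#' @param x a \linkS4class{MetricsReport}.
#' @return \code{metricValues()}: named numeric vector of the five metrics.
#' @name MetricsReport-accessors
#' @rdname MetricsReport-accessors
#' @export
setMethod("metricValues", "MetricsReport", function(x)
  c(mse = x@mse, mae = x@mae, mlre = x@mlre,
    residualVariance = x@residualVariance, mcc = x@mcc))

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport over %d gene(s), %d true CN level(s)\n",
              object@nGenes, object@nTrueCNLevels))
  v <- metricValues(object)
  for (nm in names(v)) cat(sprintf("  %-17s %.6g\n", nm, v[[nm]]))
  cat(sprintf("  confusion (micro): TP %d, TN %d, FP %d, FN %d\n",
              as.integer(object@confusion["TP"]),
              as.integer(object@confusion["TN"]),
              as.integer(object@confusion["FP"]),
              as.integer(object@confusion["FN"])))
  if (length(object@missingGenes))
    cat(sprintf("  %d truth gene(s) missing from the gene set\n",
                length(object@missingGenes)))
  invisible(NULL)
})
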