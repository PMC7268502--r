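## Readers and writers for the caller-output dialects, gene models, truth
## tables and the consensus result.  All tabular inputs are tab-separated;
## lines starting with "#" are comments; coordinates in files are either
## 0-based half-open ("zero_based", the BED convention) or 1-based closed
## ("one_based", the GFF convention) as declared by `dialect`, and are
## converted to the internal GRanges representation (1-based closed) on read.

.readTSV <- function(path, nCols, colNames, numericCols) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(stats::setNames(rep(list(character()), nCols), colNames))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < nCols)
  if (length(bad))
    stop(sprintf("%s: malformed line %d (expected %d tab-separated fields, got %d)",
                 path, lineNo[bad[1L]], nCols, nf[bad[1L]]))
  out <- lapply(seq_len(nCols), function(j)
    vapply(parts, `[[`, character(1), j))
  names(out) <- colNames
  for (j in numericCols) {
    v <- suppressWarnings(as.numeric(out[[j]]))
    bad <- which(is.na(v) & !(out[[j]] %in% c("NA", "")))
    if (length(bad))
      stop(sprintf("%s: non-numeric value '%s' in column %s at line %d",
                   path, out[[j]][bad[1L]], colNames[j], lineNo[bad[1L]]))
    if (any(!is.finite(v) & !is.na(v)))
      stop(sprintf("%s: non-finite value in column %s", path, colNames[j]))
    out[[j]] <- v
  }
  out
}

.toInternalCoords <- function(start, end, dialect) {
  if (dialect == "zero_based") start <- start + 1
  if (any(start > end))
    stop("interval with start > end after coordinate conversion")
  list(start = as.integer(start), end = as.integer(end))
}

#' Read a coverage caller's predictions
#'
#' Expects a tab-separated file with columns chrom, start, end, cn (absolute
#' copy numbers for non-overlapping bins).  Lines starting with "#" are
#' skipped.
#'
#' @param path file path.
#' @param dialect coordinate convention of the file: \code{"zero_based"}
#'   (half-open, BED-like; the default) or \code{"one_based"} (closed).
#' @return a validated coverage \linkS4class{CallerTrack}.
#' @export
readCoverageTrack <- function(path, dialect = c("zero_based", "one_based")) {
  dialect <- match.arg(dialect)
  d <- .readTSV(path, 4L, c("chrom", "start", "end", "cn"), 2:4)
  if (!length(d$chrom))
    return(CallerTrack(character(), integer(), integer(), numeric(),
                       "coverage", "absolute_cn"))
  co <- .toInternalCoords(d$start, d$end, dialect)
  CallerTrack(d$chrom, co$start, co$end, d$cn, "coverage", "absolute_cn")
}

#' Read a hybrid caller's predictions
#'
#' Columns chrom, start, end, value.  The value scale must be declared by the
#' caller of this function: log2 ratios against a matched sample may be
#' negative; ratios against a zero-coverage null alignment are relative to 0
#' and must be non-negative (negative values are rejected).  Gaps between
#' bins are preserved: the track simply makes no prediction there.
#'
#' @inheritParams readCoverageTrack
#' @param valueScale \code{"log2_vs_matched"} or \code{"ratio_vs_null"}.
#' @return a validated hybrid \linkS4class{CallerTrack}.
#' @export
readHybridTrack <- function(path, dialect = c("zero_based", "one_based"),
                            valueScale = c("ratio_vs_null",
                                           "log2_vs_matched")) {
  dialect <- match.arg(dialect)
  valueScale <- match.arg(valueScale)
  d <- .readTSV(path, 4L, c("chrom", "start", "end", "value"), 2:4)
  if (!length(d$chrom))
    return(CallerTrack(character(), integer(), integer(), numeric(),
                       "hybrid", valueScale))
  co <- .toInternalCoords(d$start, d$end, dialect)
  CallerTrack(d$chrom, co$start, co$end, d$value, "hybrid", valueScale)
}

#' Read a referee caller's calls
#'
#' Columns chrom, start, end, then either a numeric copy number or a class
#' label (\code{deletion} / \code{duplication} / \code{amplification}).
#' Magnitudes from referee callers are retained but treated as unreliable:
#' only the deletion/amplification direction is ever used downstream.
#' An empty file yields an empty track with a warning.
#'
#' @inheritParams readCoverageTrack
#' @return a validated referee \linkS4class{CallerTrack}; class-only rows
#'   have \code{value = NA} and an \code{svClass} label.
#' @export
readRefereeTrack <- function(path, dialect = c("zero_based", "one_based")) {
  dialect <- match.arg(dialect)
  d <- .readTSV(path, 4L, c("chrom", "start", "end", "call"), 2:3)
  if (!length(d$chrom)) {
    warning(sprintf("referee file %s contains no calls", path))
    return(CallerTrack(character(), integer(), integer(), numeric(),
                       "referee", "absolute_cn",
                       svClass = character()))
  }
  co <- .toInternalCoords(d$start, d$end, dialect)
  value <- suppressWarnings(as.numeric(d$call))
  svClass <- rep(NA_character_, length(value))
  isLabel <- is.na(value)
  okLabel <- d$call %in% c("deletion", "duplication", "amplification")
  if (any(isLabel & !okLabel))
    stop(sprintf("unrecognised referee call '%s'",
                 d$call[which(isLabel & !okLabel)[1L]]))
  svClass[isLabel] <- ifelse(d$call[isLabel] == "duplication",
                             "amplification", d$call[isLabel])
  CallerTrack(d$chrom, co$start, co$end, value, "referee", "absolute_cn",
              svClass = svClass)
}

#' Write consensus segments
#'
#' Emits a BED-compatible TSV (0-based half-open coordinates) with columns
#' chrom, start, end, cn_meta (one decimal), cn_meta_full (full precision),
#' error_score, rule_id, in deterministic coordinate order, preceded by a
#' "#"-prefixed header line.
#'
#' @param path output file path.
#' @param segments GRanges of consensus segments as returned by
#'   \code{\link{callConsensus}}.
#' @param comments optional character vector of "#"-prefixed provenance
#'   lines written above the header (e.g. the effective config).
#' @return the path, invisibly.
#' @export
writeConsensus <- function(path, segments, comments = character()) {
  validateConsensus(segments)
  segments <- sortByCoord(segments)
  header <- c(comments,
              "#chrom\tstart\tend\tcn_meta\tcn_meta_full\terror_score\trule_id")
  m <- S4Vectors::mcols(segments)
  rows <- if (length(segments)) {
    sprintf("%s\t%d\t%d\t%.1f\t%s\t%s\t%s",
            as.character(GenomicRanges::seqnames(segments)),
            GenomicRanges::start(segments) - 1L,
            GenomicRanges::end(segments),
            roundHalfAway(m$cnMeta),
            format(m$cnMeta, digits = 15, trim = TRUE, scientific = FALSE),
            format(m$errorScore, digits = 15, trim = TRUE,
                   scientific = FALSE),
            m$ruleId)
  } else character()
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Read consensus segments written by \code{\link{writeConsensus}}
#'
#' @param path file path.
#' @return GRanges with columns \code{cnMeta} (full precision),
#'   \code{cnMetaRounded}, \code{errorScore}, \code{ruleId}.
#' @export
readConsensus <- function(path) {
  d <- .readTSV(path, 7L,
                c("chrom", "start", "end", "cn", "cnFull", "e", "rule"),
                c(2:6))
  gr <- if (length(d$chrom)) {
    co <- .toInternalCoords(d$start, d$end, "zero_based")
    makeGR(d$chrom, co$start, co$end)
  } else GenomicRanges::GRanges()
  S4Vectors::mcols(gr)$cnMeta <- d$cnFull
  S4Vectors::mcols(gr)$cnMetaRounded <- d$cn
  S4Vectors::mcols(gr)$errorScore <- d$e
  S4Vectors::mcols(gr)$ruleId <- d$rule
  sortByCoord(gr)
}

#' Write a CallerTrack in its TSV dialect
#'
#' Inverse of the track readers: chrom, start, end, value (or class label for
#' class-only referee calls), in the requested coordinate dialect.
#'
#' @param path output path.
#' @param track a \linkS4class{CallerTrack}.
#' @param dialect \code{"zero_based"} or \code{"one_based"}.
#' @return the path, invisibly.
#' @export
writeTrack <- function(path, track,
                       dialect = c("zero_based", "one_based")) {
  dialect <- match.arg(dialect)
  gr <- track@calls
  start <- GenomicRanges::start(gr)
  if (dialect == "zero_based") start <- start - 1L
  v <- S4Vectors::mcols(gr)$value
  val <- format(v, digits = 15, trim = TRUE, scientific = FALSE)
  if ("svClass" %in% colnames(S4Vectors::mcols(gr))) {
    lab <- S4Vectors::mcols(gr)$svClass
    val[is.na(v) & !is.na(lab)] <- lab[is.na(v) & !is.na(lab)]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#%s track, scale %s, %s coordinates",
                       track@callerRole, track@valueScale, dialect),
               "#chrom\tstart\tend\tvalue",
               sprintf("%s\t%d\t%d\t%s",
                       as.character(GenomicRanges::seqnames(gr)),
                       start, GenomicRanges::end(gr), val)),
             con)
  invisible(path)
}

#' Read gene models
#'
#' GFF3/GTF files are parsed with \pkg{rtracklayer}; features of type "gene"
#' are kept (all features if no type column is present) and the gene
#' identifier is taken from \code{gene_id}, \code{ID} or \code{Name},
#' whichever exists first.  The TSV format has columns gene_id, chrom, start,
#' end and optionally strand, with 0-based half-open coordinates.  Duplicate
#' gene ids are rejected.
#'
#' @param path file path.
#' @param format \code{"gff3"}, \code{"gtf"} or \code{"tsv"}.
#' @return GRanges with metadata column \code{gene_id} (strand carried but
#'   unused by any computation).
#' @export
readGenes <- function(path, format = c("tsv", "gff3", "gtf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    d <- .readTSV(path, 4L, c("gene_id", "chrom", "start", "end"), 3:4)
    co <- .toInternalCoords(d$start, d$end, "zero_based")
    gr <- makeGR(d$chrom, co$start, co$end)
    S4Vectors::mcols(gr)$gene_id <- d$gene_id
  } else {
    imp <- rtracklayer::import(path, format = format)
    if ("type" %in% colnames(S4Vectors::mcols(imp)) &&
        any(S4Vectors::mcols(imp)$type == "gene"))
      imp <- imp[S4Vectors::mcols(imp)$type == "gene"]
    idCol <- intersect(c("gene_id", "ID", "Name"),
                       colnames(S4Vectors::mcols(imp)))
    if (!length(idCol))
      stop(sprintf("%s: no gene identifier attribute (gene_id/ID/Name) found",
                   path))
    ids <- as.character(S4Vectors::mcols(imp)[[idCol[1L]]])
    if (anyNA(ids) || any(ids == "")) {
      i <- which(is.na(ids) | ids == "")[1L]
      stop(sprintf("%s: missing gene identifier for feature at %s:%d-%d",
                   path, as.character(GenomicRanges::seqnames(imp))[i],
                   GenomicRanges::start(imp)[i], GenomicRanges::end(imp)[i]))
    }
    gr <- makeGR(as.character(GenomicRanges::seqnames(imp)),
                 GenomicRanges::start(imp), GenomicRanges::end(imp))
    GenomicRanges::strand(gr) <- GenomicRanges::strand(imp)
    S4Vectors::mcols(gr)$gene_id <- ids
  }
  dup <- duplicated(S4Vectors::mcols(gr)$gene_id)
  if (any(dup))
    stop(sprintf("duplicate gene_id '%s'",
                 S4Vectors::mcols(gr)$gene_id[which(dup)[1L]]))
  sortByCoord(gr)
}

#' Read a truth table of per-gene copy numbers
#'
#' TSV with columns gene_id, true_cn and optionally eval_length (the number
#' of bases of the gene actually covered by the truth segment, used to
#' truncate partially covered genes).  All true copy numbers must be
#' non-negative and finite.
#'
#' @param path file path.
#' @return data.frame with columns \code{gene_id}, \code{true_cn} and, when
#'   present in the file, \code{eval_length}.
#' @export
readTruthTable <- function(path) {
  lines <- readLines(path, n = 50L)
  dataLine <- lines[!grepl("^\\s*(#|$)", lines)][1L]
  hasLen <- !is.na(dataLine) &&
    length(strsplit(dataLine, "\t", fixed = TRUE)[[1L]]) >= 3L
  if (hasLen) {
    d <- .readTSV(path, 3L, c("gene_id", "true_cn", "eval_length"), 2:3)
  } else {
    d <- .readTSV(path, 2L, c("gene_id", "true_cn"), 2L)
  }
  if (any(d$true_cn < 0)) stop("true copy numbers must be non-negative")
  if (any(duplicated(d$gene_id))) stop("duplicate gene_id in truth table")
  as.data.frame(d, stringsAsFactors = FALSE)
}
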