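#' Construct a PloidyModel
#'
#' @param sex \code{"female"}, \code{"male"} or \code{"unspecified"}.  In a
#'   female model the allosomes (X, Y) get ploidy 2, in a male model 1; with
#'   \code{"unspecified"} they fall back to \code{defaultPloidy}.
#' @param defaultPloidy ploidy of autosomes (2 for the standard diploid
#'   model).
#' @param lookup optional named numeric vector of per-chromosome overrides
#'   (canonical tokens without "chr" prefix).
#' @return a \linkS4class{PloidyModel}.
#' @examples
#' ploidyAt(PloidyModel("female"), "chrX")
#' ploidyAt(PloidyModel("male"), "X")
#' @export
PloidyModel <- function(sex = c("unspecified", "female", "male"),
                        defaultPloidy = 2L, lookup = numeric()) {
  sex <- match.arg(sex)
  lk <- as.numeric(lookup)
  if (length(lookup)) names(lk) <- normalizeChrom(names(lookup))
  new("PloidyModel", defaultPloidy = as.integer(defaultPloidy), sex = sex,
      lookup = lk)
}

.AUTOSOMES <- as.character(1:22)
.ALLOSOMES <- c("X", "Y")

#' Ploidy of a chromosome under a model
#'
#' Autosomes return the default ploidy; allosomes follow the sex rule (2 if
#' female, 1 if male).  Explicit lookup entries take precedence.  An
#' unrecognised token without an override falls back to the default ploidy;
#' with \code{strict = FALSE} (default) this logs a warning, with
#' \code{strict = TRUE} it is an error.
#'
#' @param model a \linkS4class{PloidyModel}.
#' @param chrom character vector of chromosome names (any "chr" prefix
#'   accepted).
#' @param strict error instead of warn on unrecognised tokens.
#' @return numeric vector of ploidies, one per element of \code{chrom}.
#' @examples
#' ploidyAt(PloidyModel("female"), c("chr7", "chrX"))
#' @rdname ploidyAt
#' @export
setMethod("ploidyAt", "PloidyModel", function(model, chrom, strict = FALSE) {
  tok <- normalizeChrom(chrom)
  p <- rep(as.numeric(model@defaultPloidy), length(tok))
  allo <- tok %in% .ALLOSOMES
  if (model@sex == "female") p[allo] <- 2
  if (model@sex == "male")   p[allo] <- 1
  inLookup <- tok %in% names(model@lookup)
  p[inLookup] <- model@lookup[tok[inLookup]]
  unknown <- !(tok %in% c(.AUTOSOMES, .ALLOSOMES)) & !inLookup
  if (any(unknown)) {
    msg <- sprintf("unrecognised chromosome token(s) %s; using default ploidy %d",
                   paste(unique(tok[unknown]), collapse = ", "),
                   model@defaultPloidy)
    if (strict) stop(msg) else warning(msg)
  }
  p
})

setMethod("show", "PloidyModel", function(object) {
  cat(sprintf("PloidyModel: default ploidy %d, sex %s%s\n",
              object@defaultPloidy, object@sex,
              if (length(object@lookup))
                sprintf(", %d override(s)", length(object@lookup)) else ""))
  invisible(NULL)
})

#' Construct a Thresholds object
#'
#' @param t2 upper (normal vs amplification) boundary.
#' @param ploidy ploidy the thresholds refer to; \code{t1} is derived as
#'   \code{2 * ploidy - t2}.
#' @return a \linkS4class{Thresholds}.
#' @examples
#' Thresholds(2.15)
#' @export
Thresholds <- function(t2, ploidy = 2) {
  new("Thresholds", t1 = 2 * ploidy - t2, t2 = t2, ploidy = ploidy)
}

#' Accessors for Thresholds
#' @param x a \linkS4class{Thresholds}.
#' @return named numeric vector \code{c(T1 = , T2 = )}.
#' @name Thresholds-accessors
#' @rdname Thresholds-accessors
#' @export
setMethod("thresholdValues", "Thresholds",
          function(x) c(T1 = x@t1, T2 = x@t2))

setMethod("show", "Thresholds", function(object) {
  cat(sprintf("Thresholds: T1 = %g, T2 = %g (ploidy %g)\n",
              object@t1, object@t2, object@ploidy))
  invisible(NULL)
})
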