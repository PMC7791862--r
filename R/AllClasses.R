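# S4 classes for the central data objects.

#' RegionSet: a normalized set of genomic intervals
#'
#' A thin wrapper around a [GenomicRanges::GRanges] in which intervals are
#' guaranteed normalized: per-chromosome sorted, non-overlapping and
#' non-adjacent, so that every covered-base set has exactly one
#' representation. Constructed from 0-based half-open (BED-style)
#' coordinates; stored internally 1-based closed as is idiomatic for
#' GRanges.
#'
#' @slot ranges a normalized `GRanges`.
#' @export
setClass("RegionSet", representation(ranges = "GRanges"))

setValidity("RegionSet", function(object) {
  gr <- object@ranges
  norm <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  if (length(gr) != length(norm) ||
      (length(gr) > 0 && !identical(as.character(gr), as.character(norm)))) {
    return("ranges are not normalized (sorted, merged, non-adjacent)")
  }
  TRUE
})

#' BenchmarkSets: the three variant sets A, B and C
#'
#' @slot A character vector of truth variant keys inside target regions.
#' @slot B character vector of query variant keys inside target regions.
#' @slot C character vector of query variant keys inside high-confidence
#'   regions.
#'
#' Each slot is a mathematical set: unique keys in canonical sort order.
#' B and C derive from the same query call set restricted to different
#' region sets.
#' @export
setClass("BenchmarkSets",
         representation(A = "character", B = "character", C = "character"))

setValidity("BenchmarkSets", function(object) {
  for (nm in c("A", "B", "C")) {
    k <- slot(object, nm)
    if (anyDuplicated(k)) return(paste0("set ", nm, " contains duplicate keys"))
  }
  TRUE
})

#' DiscreteCounts: the six benchmark categories
#'
#' Holds the counts and the member key lists of the six pairwise-disjoint
#' categories derived from a [BenchmarkSets-class] object: tp, fp, fn,
#' nac (non-assessed calls), o (out of region of interest) and i
#' (incongruences). True negatives are not computed.
#'
#' @slot counts named integer vector (tp, fp, fn, nac, o, i).
#' @slot members named list of character key vectors, same names.
#' @export
setClass("DiscreteCounts",
         representation(counts = "integer", members = "list"))

.CATEGORIES <- c("tp", "fp", "fn", "nac", "o", "i")

setValidity("DiscreteCounts", function(object) {
  if (!identical(names(object@counts), .CATEGORIES))
    return("counts must be named tp, fp, fn, nac, o, i")
  if (!identical(names(object@members), .CATEGORIES))
    return("members must be named tp, fp, fn, nac, o, i")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (!identical(unname(object@counts),
                 vapply(object@members, length, 0L, USE.NAMES = FALSE)))
    return("counts do not match member list lengths")
  all_keys <- unlist(object@members, use.names = FALSE)
  if (anyDuplicated(all_keys))
    return("category sets are not pairwise disjoint")
  TRUE
})

#' RocResult: an ROC curve with AUC and its significance test
#'
#' @slot points data.frame with columns `threshold`, `fpr`, `tpr`;
#'   the curve starts at (0,0) and ends at (1,1).
#' @slot auc area under the curve (rank/trapezoid estimate).
#' @slot se Hanley-McNeil standard error of the AUC.
#' @slot z,p z statistic and two-sided p-value of the test against the
#'   chance AUC of 0.5.
#' @slot nPos,nNeg numbers of positive and negative calls.
#' @slot calls the scored calls (data.frame with `score`, `label` and
#'   optionally `key`), retained for paired curve comparison.
#' @export
setClass("RocResult",
         representation(points = "data.frame", auc = "numeric",
                        se = "numeric", z = "numeric", p = "numeric",
                        nPos = "integer", nNeg = "integer",
                        calls = "data.frame"))

setValidity("RocResult", function(object) {
  pts <- object@points
  if (!all(c("threshold", "fpr", "tpr") %in% names(pts)))
    return("points needs threshold, fpr, tpr columns")
  if (nrow(pts) < 2 || pts$fpr[1] != 0 || pts$tpr[1] != 0 ||
      pts$fpr[nrow(pts)] != 1 || pts$tpr[nrow(pts)] != 1)
    return("curve must start at (0,0) and end at (1,1)")
  if (object@auc < 0 || object@auc > 1) return("auc outside [0,1]")
  TRUE
})

## ---- show methods -----------------------------------------------------

setMethod("show", "RegionSet", function(object) {
  gr <- object@ranges
  cat(sprintf("RegionSet: %d interval(s) on %d chromosome(s), %s bp\n",
              length(gr), length(GenomeInfoDb::seqlevels(gr)),
              format(totalLength(object), big.mark = ",", scientific = FALSE)))
  if (length(gr) > 0) {
    df <- as.data.frame(object)
    print(utils::head(df, 5), row.names = FALSE)
    if (nrow(df) > 5) cat("...\n")
  }
  invisible(NULL)
})

setMethod("show", "BenchmarkSets", function(object) {
  cat(sprintf(
    "BenchmarkSets: |A| = %d (truth in target), |B| = %d (query in target), |C| = %d (query in confident)\n",
    length(object@A), length(object@B), length(object@C)))
  invisible(NULL)
})

setMethod("show", "DiscreteCounts", function(object) {
  cat("DiscreteCounts:\n")
  print(object@counts)
  invisible(NULL)
})

setMethod("show", "RocResult", function(object) {
  cat(sprintf("RocResult: AUC = %.4f (SE %.4f), n+ = %d, n- = %d, z = %.3f, p = %s\n",
              object@auc, object@se, object@nPos, object@nNeg,
              object@z, formatPValue(object@p)))
  invisible(NULL)
})

## ---- accessors --------------------------------------------------------

#' @describeIn BenchmarkSets-class truth keys in target regions.
#' @param x object.
#' @export
setA <- function(x) { stopifnot(is(x, "BenchmarkSets")); x@A }

#' @describeIn BenchmarkSets-class query keys in target regions.
#' @export
setB <- function(x) { stopifnot(is(x, "BenchmarkSets")); x@B }

#' @describeIn BenchmarkSets-class query keys in high-confidence regions.
#' @export
setC <- function(x) { stopifnot(is(x, "BenchmarkSets")); x@C }

#' Category counts of a DiscreteCounts object
#'
#' @param x a [DiscreteCounts-class] object.
#' @return named integer vector with elements tp, fp, fn, nac, o, i.
#' @export
categoryCounts <- function(x) {
  stopifnot(is(x, "DiscreteCounts"))
  x@counts
}

#' Member keys of one benchmark category
#'
#' @param x a [DiscreteCounts-class] object.
#' @param category one of `"tp"`, `"fp"`, `"fn"`, `"nac"`, `"o"`, `"i"`.
#' @return character vector of variant keys in canonical order.
#' @export
categoryKeys <- function(x, category = .CATEGORIES) {
  stopifnot(is(x, "DiscreteCounts"))
  category <- match.arg(category)
  x@members[[category]]
}

#' @describeIn RocResult-class the ROC points (threshold, fpr, tpr).
#' @param x object.
#' @export
rocPoints <- function(x) { stopifnot(is(x, "RocResult")); x@points }

#' @describeIn RocResult-class the area under the curve.
#' @export
auc <- function(x) { stopifnot(is(x, "RocResult")); x@auc }
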