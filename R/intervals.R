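# Genomic interval algebra: construction, normalization, intersection,
# length and point-membership queries for RegionSet objects.
#
# Coordinate conventions, fixed project-wide: BED input/output is 0-based
# half-open; VCF positions are 1-based; the internal GRanges is 1-based
# closed, so a VCF position pos lies in BED interval [start, end) iff
# start + 1 <= pos <= end.

#' Construct a RegionSet from 0-based half-open intervals
#'
#' Chromosome names are normalized (see [normalizeChrom()]) and the
#' intervals are reduced to canonical form: per-chromosome sorted, with
#' overlapping and adjacent intervals merged.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; 0-based half-open, `0 <= start < end`.
#' @return a [RegionSet-class] object.
#' @examples
#' RegionSet(c("1", "1"), c(0, 5), c(10, 20))  # merges to 1:[0,20)
#' @export
RegionSet <- function(chrom = character(), start = integer(), end = integer()) {
  stopifnot(length(start) == length(end))
  if (length(chrom) == 1 && length(start) > 1) chrom <- rep(chrom, length(start))
  stopifnot(length(chrom) == length(start))
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) > 0) {
    bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
    if (length(bad) > 0)
      stop("invalid interval at index ", bad[1], ": start=", start[bad[1]],
           " end=", end[bad[1]], " (need 0 <= start < end)")
  }
  chrom <- normalizeChrom(chrom)
  lev <- unique(chrom)
  lev <- lev[order(.chromRank(lev))]
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = lev),
    ranges = IRanges::IRanges(start = start + 1, end = end)
  )
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  new("RegionSet", ranges = gr)
}

.regionSetFromGRanges <- function(gr) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1,
                   end = BiocGenerics::end(gr))
  RegionSet(df$chrom, df$start, df$end)
}

#' @describeIn RegionSet as a data.frame of 0-based half-open intervals
#'   (columns `chrom`, `start`, `end`).
#' @param x a RegionSet.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "RegionSet", function(x, ...) {
  gr <- x@ranges
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1,
             end = BiocGenerics::end(gr),
             stringsAsFactors = FALSE)
})

#' @describeIn RegionSet number of intervals.
#' @export
setMethod("length", "RegionSet", function(x) length(x@ranges))

#' Total number of bases covered by a RegionSet
#'
#' @param x a [RegionSet-class] object.
#' @return integer-valued numeric: the sum of interval lengths.
#' @examples
#' totalLength(RegionSet(c("1", "2"), c(0, 0), c(10, 5)))  # 15
#' @export
setGeneric("totalLength", function(x) standardGeneric("totalLength"))

#' @rdname totalLength
#' @export
setMethod("totalLength", "RegionSet", function(x) {
  sum(as.numeric(BiocGenerics::width(x@ranges)))
})

# Put two GRanges on a shared seqlevels universe so set operations work.
.harmonize <- function(a, b) {
  lev <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  lev <- lev[order(.chromRank(lev))]
  GenomeInfoDb::seqlevels(a) <- lev
  GenomeInfoDb::seqlevels(b) <- lev
  list(a = a, b = b)
}

#' Intersect two RegionSets
#'
#' Returns exactly the bases covered by both inputs, in normalized form.
#' Intersection is commutative and idempotent, and
#' `totalLength(intersect(a, b)) <= min(totalLength(a), totalLength(b))`.
#'
#' @param x,y [RegionSet-class] objects.
#' @return a normalized [RegionSet-class].
#' @examples
#' intersect(RegionSet("1", 0, 10), RegionSet("1", 5, 20))  # 1:[5,10)
#' @export
setMethod("intersect", signature("RegionSet", "RegionSet"), function(x, y) {
  h <- .harmonize(x@ranges, y@ranges)
  .regionSetFromGRanges(GenomicRanges::intersect(h$a, h$b))
})

#' Test whether 1-based positions fall inside a RegionSet
#'
#' A VCF position `pos` (1-based) lies inside BED interval `[start, end)`
#' iff `start < pos <= end`; a multi-base variant counts as inside iff its
#' POS base is covered (sufficient for the SNP scope of the benchmark).
#'
#' @param x a [RegionSet-class] object.
#' @param chrom character vector of chromosome names (any "chr" dialect).
#' @param pos integer vector of 1-based positions, parallel to `chrom`.
#' @return logical vector.
#' @examples
#' containsPos(RegionSet("1", 100, 200), "chr1", c(100, 101, 200, 201))
#' @export
setGeneric("containsPos", function(x, chrom, pos) standardGeneric("containsPos"))

#' @rdname containsPos
#' @export
setMethod("containsPos", "RegionSet", function(x, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  out <- logical(length(pos))
  if (length(pos) == 0 || length(x@ranges) == 0) return(out)
  chrom <- normalizeChrom(chrom)
  pos <- as.numeric(pos)
  gr <- x@ranges
  rchrom <- as.character(GenomeInfoDb::seqnames(gr))
  rstart <- BiocGenerics::start(gr)  # 1-based inclusive
  rend <- BiocGenerics::end(gr)
  for (ch in unique(chrom)) {
    sel <- rchrom == ch
    if (!any(sel)) next
    qs <- which(chrom == ch)
    idx <- findInterval(pos[qs], rstart[sel])
    hit <- idx >= 1
    hit[hit] <- pos[qs][hit] <= rend[sel][idx[hit]]
    out[qs] <- hit
  }
  out
})

#' Restrict variant keys to a RegionSet
#'
#' Keeps exactly the keys whose position lies inside the region set;
#' input order is preserved.
#'
#' @param keys character vector of variant keys (see [makeKeys()]).
#' @param regions a [RegionSet-class] object.
#' @return the surviving keys, in input order.
#' @export
subsetKeys <- function(keys, regions) {
  stopifnot(is(regions, "RegionSet"))
  if (length(keys) == 0) return(keys)
  f <- parseKeys(keys)
  keys[containsPos(regions, f$chrom, f$pos)]
}
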