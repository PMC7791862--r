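# Variant keys: the normalized identity "chrom:pos:ref:alt" (optionally
# ":gt" in genotype-aware mode) under which all set membership is decided.

#' Normalize chromosome names
#'
#' Strips a leading "chr" prefix (case-insensitively) and upper-cases the
#' remainder so that GRCh37-style ("1", "X") and UCSC-style ("chr1",
#' "chrX") names compare equal.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector of normalized names.
#' @examples
#' normalizeChrom(c("chr1", "1", "chrX", "mt"))
#' @export
normalizeChrom <- function(chrom) {
  toupper(sub("^chr", "", as.character(chrom), ignore.case = TRUE))
}

# Sort rank for chromosome names: numeric first in numeric order, then
# X, Y, MT, then anything else alphabetically.
.chromRank <- function(chrom) {
  r <- suppressWarnings(as.numeric(chrom))
  r[chrom == "X"] <- 23
  r[chrom == "Y"] <- 24
  r[chrom %in% c("M", "MT")] <- 25
  unk <- is.na(r)
  if (any(unk)) {
    lev <- sort(unique(chrom[unk]))
    r[unk] <- 25 + match(chrom[unk], lev)
  }
  r
}

#' Build variant key strings
#'
#' @param chrom,pos,ref,alt parallel vectors describing one SNP per
#'   element; `chrom` is normalized, alleles are upper-cased.
#' @param gt optional normalized genotype string appended as a fifth
#'   field for genotype-aware matching.
#' @return character vector of keys, `"chrom:pos:ref:alt"`.
#' @examples
#' makeKeys("chr1", 100, "c", "t")
#' @export
makeKeys <- function(chrom, pos, ref, alt, gt = NULL) {
  k <- paste(normalizeChrom(chrom), as.integer(pos),
             toupper(ref), toupper(alt), sep = ":")
  if (!is.null(gt)) k <- paste(k, gt, sep = ":")
  k
}

#' Parse variant key strings back into fields
#'
#' @param keys character vector of keys produced by [makeKeys()] or
#'   [toKeys()].
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt` and,
#'   when present, `gt`.
#' @export
parseKeys <- function(keys) {
  if (length(keys) == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, ":", fixed = TRUE)
  n <- lengths(parts)
  if (any(n < 4)) stop("malformed variant key: ", keys[which(n < 4)[1]])
  out <- data.frame(
    chrom = vapply(parts, `[[`, "", 1),
    pos   = as.integer(vapply(parts, `[[`, "", 2)),
    ref   = vapply(parts, `[[`, "", 3),
    alt   = vapply(parts, `[[`, "", 4),
    stringsAsFactors = FALSE
  )
  if (any(n >= 5)) {
    out$gt <- vapply(parts, function(p) {
      if (length(p) >= 5) paste(p[5:length(p)], collapse = ":") else NA_character_
    }, "")
  }
  out
}

#' Sort variant keys deterministically
#'
#' Orders by chromosome (natural order: 1..22, X, Y, MT, then others
#' alphabetically), then position, reference allele and alternate allele.
#'
#' @param keys character vector of keys.
#' @return the keys in canonical order.
#' @export
sortKeys <- function(keys) {
  if (length(keys) <= 1) return(keys)
  f <- parseKeys(keys)
  keys[order(.chromRank(f$chrom), f$pos, f$ref, f$alt)]
}
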