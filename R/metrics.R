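# Continuous benchmarking metrics and call-set summary statistics.
#
# Undefined metrics (zero denominators) return NA_real_, never 0 or 1,
# so degenerate inputs stay visible. Internal computation is unrounded;
# reporting functions round: 3 decimals for recall/precision/Frac_NA/F1,
# 5 for the Ts/Tv ratio, 4 for the missense/silent ratio.

#' Recall (sensitivity)
#'
#' The ability to detect variants known to be present: TP / (TP + FN).
#'
#' @param tp,fn non-negative integer counts.
#' @return `tp / (tp + fn)`, or `NA` when `tp + fn == 0`.
#' @examples
#' recall(233, 0)
#' @export
recall <- function(tp, fn) {
  stopifnot(tp >= 0, fn >= 0)
  if (tp + fn == 0) return(NA_real_)
  tp / (tp + fn)
}

#' Precision (positive predictive value)
#'
#' The ability to avoid calling variants that are not there:
#' TP / (TP + FP).
#'
#' @param tp,fp non-negative integer counts.
#' @return `tp / (tp + fp)`, or `NA` when `tp + fp == 0`.
#' @examples
#' precision(233, 3)  # 0.987 at 3 decimals
#' @export
precision <- function(tp, fp) {
  stopifnot(tp >= 0, fp >= 0)
  if (tp + fp == 0) return(NA_real_)
  tp / (tp + fp)
}

#' Fraction of non-assessed calls
#'
#' NAC divided by the total number of query calls in target regions
#' (|B| = TP + FP + NAC).
#'
#' @param nac,total non-negative integer counts.
#' @return `nac / total`, or `NA` when `total == 0`.
#' @examples
#' fracNA(23, 259)  # 0.089 at 3 decimals
#' @export
fracNA <- function(nac, total) {
  stopifnot(nac >= 0, total >= 0)
  if (total == 0) return(NA_real_)
  nac / total
}

#' F1 score
#'
#' Harmonic mean of precision and recall, computed from their unrounded
#' values: 2PR / (P + R).
#'
#' @param precision,recall reals in \[0, 1\].
#' @return the F1 score, or `NA` when both are zero or either is `NA`.
#' @examples
#' f1Score(0.5, 1)  # 2/3
#' @export
f1Score <- function(precision, recall) {
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) return(NA_real_)
  2 * precision * recall / (precision + recall)
}

#' Continuous metrics from discrete category counts
#'
#' @param x a [DiscreteCounts-class] object.
#' @return named list: `recall`, `precision`, `frac_na` (denominator
#'   |B| = tp + fp + nac) and `f1`, all unrounded; `NA` where undefined.
#' @export
continuousMetrics <- function(x) {
  stopifnot(is(x, "DiscreteCounts"))
  ct <- x@counts
  p <- precision(ct[["tp"]], ct[["fp"]])
  r <- recall(ct[["tp"]], ct[["fn"]])
  list(recall = r, precision = p,
       frac_na = fracNA(ct[["nac"]], ct[["tp"]] + ct[["fp"]] + ct[["nac"]]),
       f1 = f1Score(p, r))
}

#' One benchmark report row (TP, FP, FN, I, NAC, Recall, Precision,
#' Frac_NA, F1)
#'
#' Column order and rounding follow the conventional benchmark table for
#' targeted panels: counts first, then the four ratios at 3 decimals.
#'
#' @param x a [DiscreteCounts-class] object.
#' @param caller optional caller name for the first column.
#' @param digits decimals for the ratio columns; `NULL` for unrounded.
#' @return a one-row data.frame.
#' @export
metricsRow <- function(x, caller = NULL, digits = 3) {
  ct <- categoryCounts(x)
  m <- continuousMetrics(x)
  rnd <- function(v) if (is.null(digits)) v else round(v, digits)
  row <- data.frame(
    TP = ct[["tp"]], FP = ct[["fp"]], FN = ct[["fn"]],
    I = ct[["i"]], NAC = ct[["nac"]],
    Recall = rnd(m$recall), Precision = rnd(m$precision),
    Frac_NA = rnd(m$frac_na), F1_Score = rnd(m$f1),
    stringsAsFactors = FALSE
  )
  if (!is.null(caller)) row <- cbind(Caller = caller, row,
                                     stringsAsFactors = FALSE)
  row
}

#' Transition/transversion counts and ratio
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine
#' substitutions A<->G and C<->T; all other single-base substitutions are
#' transversions. Keys whose alleles are not single A/C/G/T bases are
#' ignored.
#'
#' @param keys character vector of variant keys.
#' @return list with integer `ts`, `tv` and `ratio` = ts/tv (5-decimal
#'   reporting is left to the caller; the value is unrounded; `NA` when
#'   tv is 0).
#' @examples
#' tsTv(makeKeys(c("1", "1"), 1:2, c("A", "C"), c("G", "A")))
#' @export
tsTv <- function(keys) {
  f <- parseKeys(unique(keys))
  ok <- f$ref %in% c("A", "C", "G", "T") & f$alt %in% c("A", "C", "G", "T") &
    f$ref != f$alt
  pair <- paste0(pmin(f$ref[ok], f$alt[ok]), pmax(f$ref[ok], f$alt[ok]))
  ts <- sum(pair %in% c("AG", "CT"))
  tv <- sum(ok) - ts
  list(ts = as.integer(ts), tv = as.integer(tv),
       ratio = if (tv == 0) NA_real_ else ts / tv)
}

#' Functional-class tallies (missense / silent)
#'
#' Counts transcript-level effect annotations across all records, so the
#' totals can exceed the number of variants (one variant may hit several
#' transcripts). Labels `missense_variant`/`missense` count as missense;
#' `synonymous_variant`/`silent` as silent; anything else is tallied
#' under `other` and ignored by the ratio.
#'
#' @param records record data.frame carrying an `effects` list-column.
#' @return list with integer `missense`, `silent`, `other` and `ratio` =
#'   missense/silent (`NA` when silent is 0).
#' @export
functionalClass <- function(records) {
  stopifnot(is.data.frame(records))
  effs <- if (nrow(records) == 0) character() else
    unlist(lapply(records$effects, function(e) e$effect), use.names = FALSE)
  missense <- sum(effs %in% c("missense_variant", "missense"))
  silent <- sum(effs %in% c("synonymous_variant", "silent"))
  list(missense = as.integer(missense), silent = as.integer(silent),
       other = as.integer(length(effs) - missense - silent),
       ratio = if (silent == 0) NA_real_ else missense / silent)
}

#' Per-chromosome variant counts
#'
#' @param keys character vector of variant keys.
#' @return named integer vector (chromosomes in natural order); counts
#'   sum to `length(keys)`.
#' @export
perChromosomeCounts <- function(keys) {
  if (length(keys) == 0) return(setNames(integer(), character()))
  chrom <- parseKeys(keys)$chrom
  lev <- unique(chrom)
  lev <- lev[order(.chromRank(lev))]
  tab <- table(factor(chrom, levels = lev))
  setNames(as.integer(tab), names(tab))
}

#' Variant rate denominator
#'
#' The "1 variant per N bases" summary: `round(span / n)`. The default
#' span is the GRCh37 primary-assembly total ([GRCH37_SPAN]); pass the
#' covered target length instead to express an on-panel rate.
#'
#' @param n number of variants.
#' @param span reference span in bases.
#' @return integer denominator N, or `NA` when `n == 0`.
#' @examples
#' variantRate(10, 100)  # one variant per 10 bases
#' @export
variantRate <- function(n, span = GRCH37_SPAN) {
  stopifnot(n >= 0, span > 0)
  if (n == 0) return(NA_real_)
  round(span / n)
}

# "0.000"-style p-value formatting used in reports: values below 5e-4
# print as 0.000; exact values are retained in JSON output.
formatPValue <- function(p, digits = 3) {
  ifelse(is.na(p), "NA", sprintf(paste0("%.", digits, "f"), p))
}
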