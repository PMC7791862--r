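# ROC curves, rank AUC, Hanley-McNeil significance and curve comparison.

#' Score query calls against the truth set
#'
#' Builds the scored-call table behind the ROC analysis: one row per
#' assessed query call in the target regions (set B), labelled positive
#' when the call is present in the truth set A, with the call's QUAL as
#' the score. Both the label and score construction are deliberately
#' simple and explicit; alternatives can be supplied by building the
#' data.frame directly.
#'
#' @param records filtered query record data.frame ([readVariants()] +
#'   [applyQualityFilters()]).
#' @param sets a [BenchmarkSets-class] object for this query.
#' @param snpOnly passed to [toKeys()].
#' @return data.frame with columns `key`, `score`, `label`; one row per
#'   unique key in B (the maximal QUAL is kept for duplicate keys).
#' @export
scoredCalls <- function(records, sets, snpOnly = TRUE) {
  stopifnot(is.data.frame(records), is(sets, "BenchmarkSets"))
  keyList <- lapply(seq_len(nrow(records)), function(j)
    toKeys(records[j, , drop = FALSE], snpOnly = snpOnly))
  n <- lengths(keyList)
  df <- data.frame(key = unlist(keyList, use.names = FALSE),
                   score = rep(records$qual, n),
                   stringsAsFactors = FALSE)
  df <- df[df$key %in% sets@B, , drop = FALSE]
  if (nrow(df) > 0) {
    df <- df[order(df$key, -df$score), , drop = FALSE]
    df <- df[!duplicated(df$key), , drop = FALSE]
  }
  df$label <- df$key %in% sets@A
  df[order(match(df$key, sortKeys(df$key))), , drop = FALSE]
}

.checkCalls <- function(calls) {
  stopifnot(is.data.frame(calls), all(c("score", "label") %in% names(calls)))
  label <- as.logical(calls$label)
  score <- as.numeric(calls$score)
  if (anyNA(score) || any(!is.finite(score))) stop("scores must be finite")
  if (anyNA(label)) stop("labels must be TRUE/FALSE")
  if (!any(label)) stop("no positive calls: ROC undefined without the positive class")
  if (all(label)) stop("no negative calls: ROC undefined without the negative class")
  list(score = score, label = label)
}

#' Rank-based AUC (Mann-Whitney)
#'
#' The probability that a randomly chosen positive call outscores a
#' randomly chosen negative one, with ties given half credit. Equals the
#' trapezoidal area under the ROC curve.
#'
#' @param calls data.frame with numeric `score` and logical `label`.
#' @return the AUC in \[0, 1\].
#' @examples
#' aucRank(data.frame(score = c(3, 4, 1, 2), label = c(TRUE, TRUE, FALSE, FALSE)))
#' @export
aucRank <- function(calls) {
  cl <- .checkCalls(calls)
  np <- sum(cl$label); nn <- sum(!cl$label)
  r <- rank(cl$score)  # midranks: ties get half credit
  (sum(r[cl$label]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve with AUC and significance
#'
#' Sweeps the decision threshold over the distinct scores in descending
#' order (tied scores grouped at one threshold), computing the false- and
#' true-positive rates at each, and estimates the AUC (trapezoidal, equal
#' to the rank AUC), its Hanley-McNeil standard error, and the two-sided
#' z-test against the chance AUC of 0.5.
#'
#' @param calls data.frame with numeric `score`, logical `label` and
#'   optionally `key` (retained for paired comparison).
#' @return a [RocResult-class] object.
#' @export
rocCurve <- function(calls) {
  cl <- .checkCalls(calls)
  np <- sum(cl$label); nn <- sum(!cl$label)
  ord <- order(cl$score, decreasing = TRUE)
  score <- cl$score[ord]; label <- cl$label[ord]
  grp <- !duplicated(score)                # one point per distinct score
  tpCum <- cumsum(label); fpCum <- cumsum(!label)
  last <- c(which(grp)[-1] - 1L, length(score))
  pts <- data.frame(
    threshold = c(Inf, score[grp]),
    fpr = c(0, fpCum[last] / nn),
    tpr = c(0, tpCum[last] / np)
  )
  a <- aucRank(calls)
  se <- aucSE(a, np, nn)
  zt <- aucTest(a, se)
  keep <- calls[, intersect(c("key", "score", "label"), names(calls)),
                drop = FALSE]
  new("RocResult", points = pts, auc = a, se = se, z = zt[["z"]],
      p = zt[["p"]], nPos = as.integer(np), nNeg = as.integer(nn),
      calls = keep)
}

# Trapezoidal area under emitted points (used as an internal cross-check
# and exposed for tests).
trapezoidAuc <- function(points) {
  f <- points$fpr; t <- points$tpr
  sum(diff(f) * (t[-1] + t[-length(t)]) / 2)
}

#' Hanley-McNeil standard error of an AUC estimate
#'
#' Closed form from the exponential-model approximation:
#' with Q1 = A/(2-A) and Q2 = 2A^2/(1+A),
#' `SE = sqrt((A(1-A) + (nPos-1)(Q1-A^2) + (nNeg-1)(Q2-A^2)) / (nPos*nNeg))`.
#' At A = 0.5 this reduces exactly to the null Mann-Whitney variance
#' `(nPos + nNeg + 1) / (12 nPos nNeg)`; at A = 1 it is 0.
#'
#' @param auc AUC estimate in \[0, 1\].
#' @param nPos,nNeg class sizes (>= 1).
#' @return the standard error (non-negative).
#' @export
aucSE <- function(auc, nPos, nNeg) {
  stopifnot(auc >= 0, auc <= 1, nPos >= 1, nNeg >= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (nPos - 1) * (q1 - auc^2) +
          (nNeg - 1) * (q2 - auc^2)) / (nPos * nNeg)
  sqrt(max(v, 0))
}

#' Test an AUC against a null value
#'
#' Normal z-test: `z = (auc - nullAuc) / se`, two-sided p.
#'
#' @param auc AUC estimate.
#' @param se its standard error.
#' @param nullAuc null hypothesis value (default 0.5, chance level).
#' @return named numeric vector `c(z = ..., p = ...)`. With `se = 0` the
#'   p-value is 1 when `auc == nullAuc` and 0 otherwise (z is `+-Inf`).
#' @examples
#' aucTest(0.75, 0.05)  # z = 5
#' @export
aucTest <- function(auc, se, nullAuc = 0.5) {
  stopifnot(se >= 0)
  if (se == 0) {
    if (auc == nullAuc) return(c(z = 0, p = 1))
    return(c(z = sign(auc - nullAuc) * Inf, p = 0))
  }
  z <- (auc - nullAuc) / se
  c(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Compare the AUCs of two ROC results
#'
#' Unpaired mode (default): `z = (A_a - A_b) / sqrt(se_a^2 + se_b^2)`
#' with Hanley-McNeil standard errors, two-sided normal p. Paired mode:
#' DeLong covariance computed on the calls whose keys appear in both
#' results (labels must agree on shared keys).
#'
#' @param a,b [RocResult-class] objects.
#' @param paired use the DeLong paired test on shared keys.
#' @return named numeric vector `c(z = ..., p = ...)`; swapping `a` and
#'   `b` negates z.
#' @export
compareAuc <- function(a, b, paired = FALSE) {
  stopifnot(is(a, "RocResult"), is(b, "RocResult"))
  if (!paired) {
    denom <- sqrt(a@se^2 + b@se^2)
    if (denom == 0) {
      if (a@auc == b@auc) return(c(z = 0, p = 1))
      return(c(z = sign(a@auc - b@auc) * Inf, p = 0))
    }
    z <- (a@auc - b@auc) / denom
    return(c(z = z, p = 2 * stats::pnorm(-abs(z))))
  }
  if (!("key" %in% names(a@calls)) || !("key" %in% names(b@calls)))
    stop("paired comparison requires calls with keys")
  shared <- intersect(a@calls$key, b@calls$key)
  if (length(shared) == 0)
    stop("paired comparison impossible: no shared keys between the two call sets")
  ca <- a@calls[match(shared, a@calls$key), ]
  cb <- b@calls[match(shared, b@calls$key), ]
  if (!identical(as.logical(ca$label), as.logical(cb$label)))
    stop("labels disagree on shared keys; paired comparison undefined")
  label <- as.logical(ca$label)
  if (!any(label) || all(label))
    stop("shared keys contain a single class; paired comparison undefined")
  .delongPaired(ca$score, cb$score, label)
}

# DeLong (1988) paired AUC comparison via placement values.
.delongPaired <- function(scoreA, scoreB, label) {
  psi <- function(x, y) {
    m <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
    m
  }
  stats <- lapply(list(scoreA, scoreB), function(s) {
    x <- s[label]; y <- s[!label]
    m <- psi(x, y)
    list(auc = mean(m), v10 = rowMeans(m), v01 = colMeans(m))
  })
  m <- sum(label); n <- sum(!label)
  if (m < 2 || n < 2)
    stop("paired comparison needs at least two shared calls per class")
  s10 <- stats::cov(cbind(stats[[1]]$v10, stats[[2]]$v10))
  s01 <- stats::cov(cbind(stats[[1]]$v01, stats[[2]]$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- stats[[1]]$auc - stats[[2]]$auc
  if (v <= 0) {
    if (d == 0) return(c(z = 0, p = 1))
    return(c(z = sign(d) * Inf, p = 0))
  }
  z <- d / sqrt(v)
  c(z = z, p = 2 * stats::pnorm(-abs(z)))
}
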