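# ROC construction, rank AUC, Hanley-McNeil significance, comparison.

test_that("analytic ROC cases: perfect separation and chance", {
  perfect <- data.frame(score = c(3, 4, 1, 2),
                        label = c(TRUE, TRUE, FALSE, FALSE))
  r <- rocCurve(perfect)
  expect_equal(auc(r), 1)
  pts <- rocPoints(r)
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(any(pts$fpr == 0 & pts$tpr == 1))  # passes through (0,1)
  expect_equal(r@se, 0)                          # Q1 = Q2 = 1 limit
  expect_equal(formatPValue(r@p), "0.000")

  allTie <- data.frame(score = c(1, 1), label = c(TRUE, FALSE))
  expect_equal(aucRank(allTie), 0.5)

  # perfectly interleaved distinct scores sit at chance up to the phase:
  # the two phases bracket 0.5 symmetrically and average to it exactly
  phase1 <- data.frame(score = 1:50, label = rep(c(TRUE, FALSE), 25))
  phase2 <- data.frame(score = 1:50, label = rep(c(FALSE, TRUE), 25))
  expect_equal((aucRank(phase1) + aucRank(phase2)) / 2, 0.5, tolerance = 1e-12)
  expect_equal(aucRank(phase1), 0.5, tolerance = 0.05)

  expect_equal(aucRank(data.frame(score = c(2, 1), label = c(TRUE, FALSE))), 1)
  expect_error(rocCurve(data.frame(score = 1:3, label = rep(TRUE, 3))),
               "negative")
  expect_error(rocCurve(data.frame(score = 1:3, label = rep(FALSE, 3))),
               "positive")
})

test_that("rank AUC equals trapezoidal AUC and the pair-counting oracle", {
  set.seed(808)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    calls <- data.frame(
      score = round(rnorm(n), sample(c(0, 1, 3), 1)),  # force some ties
      label = sample(c(TRUE, FALSE), n, replace = TRUE)
    )
    if (!any(calls$label) || all(calls$label)) next
    r <- rocCurve(calls)
    expect_equal(auc(r), vcbench:::trapezoidAuc(rocPoints(r)),
                 tolerance = 1e-12)
    expect_equal(aucRank(calls), oracleAuc(calls$score, calls$label),
                 tolerance = 1e-12)
    # negating scores and flipping labels preserves the AUC
    flipped <- data.frame(score = -calls$score, label = !calls$label)
    expect_equal(aucRank(flipped), aucRank(calls), tolerance = 1e-12)
  }
})

test_that("Hanley-McNeil SE: closed form, limits and monotonicity", {
  # at AUC = 0.5 the closed form reduces exactly to the null
  # Mann-Whitney SD sqrt((nPos + nNeg + 1) / (12 nPos nNeg))
  for (n in c(10, 50, 100))
    expect_equal(aucSE(0.5, n, n), sqrt((2 * n + 1) / (12 * n * n)),
                 tolerance = 1e-12)
  expect_equal(aucSE(1, 30, 40), 0)
  ses <- sapply(c(10, 20, 40, 80, 160), function(n) aucSE(0.8, n, n))
  expect_true(all(diff(ses) < 0))
})

test_that("AUC z-test against chance", {
  expect_equal(aucTest(0.5, 0.05), c(z = 0, p = 1))
  zt <- aucTest(0.75, 0.05)
  expect_equal(zt[["z"]], 5)
  expect_equal(zt[["p"]], 2 * pnorm(-5), tolerance = 1e-12)
  expect_equal(round(zt[["p"]], 10), 5.733e-07, tolerance = 1e-3)
  # degenerate SE
  expect_equal(aucTest(1, 0)[["p"]], 0)
  expect_equal(formatPValue(aucTest(1, 0)[["p"]]), "0.000")
  expect_equal(aucTest(0.5, 0)[["p"]], 1)
})

test_that("compareAuc: identity, antisymmetry, and the paired DeLong path", {
  set.seed(909)
  calls <- data.frame(key = paste0("k", 1:60),
                      score = rnorm(60) + rep(c(1, 0), each = 30),
                      label = rep(c(TRUE, FALSE), each = 30))
  a <- rocCurve(calls)
  expect_equal(compareAuc(a, a), c(z = 0, p = 1))

  calls2 <- calls; calls2$score <- rnorm(60) + rep(c(0.3, 0), each = 30)
  b <- rocCurve(calls2)
  ab <- compareAuc(a, b); ba <- compareAuc(b, a)
  expect_equal(ab[["z"]], -ba[["z"]])
  expect_equal(ab[["p"]], ba[["p"]])

  pr <- compareAuc(a, b, paired = TRUE)
  expect_true(pr[["p"]] >= 0 && pr[["p"]] <= 1)
  expect_equal(compareAuc(a, a, paired = TRUE)[["z"]], 0)

  noShare <- calls2; noShare$key <- paste0("other", 1:60)
  expect_error(compareAuc(a, rocCurve(noShare), paired = TRUE), "shared")
})

test_that("a planted AUC separation is detected in at least 90% of replicates", {
  set.seed(1010)
  hits <- 0
  for (rep in 1:100) {
    n <- 100  # 200 calls per pipeline
    strong <- data.frame(score = c(rnorm(n, 2), rnorm(n)),
                         label = rep(c(TRUE, FALSE), each = n))
    weak <- data.frame(score = c(rnorm(n, 0.5), rnorm(n)),
                       label = rep(c(TRUE, FALSE), each = n))
    p <- compareAuc(rocCurve(strong), rocCurve(weak))[["p"]]
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("null p-values are uniform (Kolmogorov-Smirnov at alpha = 0.01)", {
  set.seed(1)
  n <- 50
  nullSe <- aucSE(0.5, n, n)
  p <- replicate(2000, {
    calls <- data.frame(score = rnorm(2 * n),
                        label = rep(c(TRUE, FALSE), each = n))
    aucTest(aucRank(calls), nullSe)[["p"]]
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("scoredCalls labels set-A membership and keeps one score per key", {
  target <- RegionSet("1", 0, 1000)
  confident <- RegionSet("1", 0, 1000)
  truth <- c("1:10:A:G", "1:20:C:T")
  rec <- keysToRecords(c("1:10:A:G", "1:30:G:A", "1:30:G:A"),
                       qual = c(90, 40, 55), depth = 30)
  sets <- buildSets(truth, toKeys(rec), target, confident)
  sc <- scoredCalls(rec, sets)
  expect_equal(nrow(sc), 2)                      # duplicate key collapsed
  expect_equal(sc$score[sc$key == "1:30:G:A"], 55)  # max QUAL kept
  expect_equal(sc$label, c(TRUE, FALSE))
})
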