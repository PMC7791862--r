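# End-to-end benchmark and ROC reports over files.

makeBundleDir <- function(...) {
  d <- tempfile()
  generateFixture(fixtureSpec(...), dir = d)
  d
}

test_that("runBenchmark recovers planted counts and writes a complete report", {
  d <- makeBundleDir(tp = 30, fp = 4, nac = 5, o = 2, i = 1, decoys = 3,
                     seed = 41)
  out <- tempfile()
  res <- runBenchmark(file.path(d, "truth.vcf"),
                      c(mycaller = file.path(d, "query.vcf")),
                      file.path(d, "target.bed"), file.path(d, "confident.bed"),
                      outdir = out, quiet = TRUE)
  m <- res$metrics
  expect_equal(m$TP, 30L); expect_equal(m$FP, 4L)
  expect_equal(m$NAC, 5L); expect_equal(m$I, 1L); expect_equal(m$FN, 0L)
  expect_equal(m$Recall, 1)
  expect_equal(m$Precision, round(30 / 34, 3))
  expect_equal(m$Frac_NA, round(5 / 39, 3))

  expect_true(file.exists(file.path(out, "metrics.tsv")))
  expect_true(file.exists(file.path(out, "metrics.json")))
  for (cat in c("tp", "fp", "fn", "nac", "o", "i"))
    expect_true(file.exists(file.path(out, "mycaller", paste0(cat, ".vcf"))))

  # every number in the TSV is re-derivable from the category VCFs
  tsv <- read.delim(file.path(out, "metrics.tsv"))
  for (cat in c("tp", "fp", "fn", "nac", "i")) {
    nk <- length(toKeys(readVariants(file.path(out, "mycaller",
                                               paste0(cat, ".vcf")))))
    expect_equal(tsv[[toupper(cat)]], nk)
  }
  expect_equal(tsv$Precision, round(tsv$TP / (tsv$TP + tsv$FP), 3))
})

test_that("reports are deterministic and multi-caller runs add concordance", {
  d <- makeBundleDir(tp = 10, fp = 2, nac = 3, seed = 61)
  o1 <- tempfile(); o2 <- tempfile()
  q2 <- c(a = file.path(d, "query.vcf"), b = file.path(d, "query.vcf"))
  args <- list(file.path(d, "truth.vcf"), q2, file.path(d, "target.bed"),
               file.path(d, "confident.bed"), quiet = TRUE)
  r1 <- do.call(runBenchmark, c(args, outdir = o1))
  r2 <- do.call(runBenchmark, c(args, outdir = o2))
  expect_identical(readLines(file.path(o1, "metrics.tsv")),
                   readLines(file.path(o2, "metrics.tsv")))
  expect_equal(nrow(r1$metrics), 2)
  expect_true(file.exists(file.path(o1, "concordance.tsv")))
  cells <- read.delim(file.path(o1, "concordance.tsv"))
  expect_equal(cells$count[cells$sets == "a&b"], 15L)  # identical call sets
})

test_that("an empty confident region set degrades gracefully", {
  d <- makeBundleDir(tp = 8, fp = 2, nac = 3, seed = 71)
  # overwrite confident.bed with an empty region set
  writeLines(character(), file.path(d, "confident.bed"))
  expect_warning(
    res <- runBenchmark(file.path(d, "truth.vcf"),
                        c(q = file.path(d, "query.vcf")),
                        file.path(d, "target.bed"),
                        file.path(d, "confident.bed"), quiet = TRUE),
    "high-confidence")
  m <- res$metrics
  # C is empty: fp/fn/o vanish; planted fp and nac merge into NAC = |B \ A|
  expect_equal(m$FP, 0L); expect_equal(m$FN, 0L)
  expect_equal(m$NAC, 5L)
  expect_equal(m$TP, 8L)   # tp unaffected: A n B needs no confident region
  expect_equal(m$I, 0L)
})

test_that("undefined metrics surface as NA, not as 0 or 1", {
  d <- makeBundleDir(nac = 4, seed = 81)  # no truth variants at all
  res <- runBenchmark(file.path(d, "truth.vcf"),
                      c(q = file.path(d, "query.vcf")),
                      file.path(d, "target.bed"),
                      file.path(d, "confident.bed"), quiet = TRUE)
  expect_true(is.na(res$metrics$Recall))    # tp + fn = 0
  expect_equal(res$metrics$NAC, 4L)
})

test_that("runRocReport separates planted quality gaps and compares pipelines", {
  d <- tempfile()
  generateFixture(fixtureSpec(tp = 60, fp = 25, nac = 15,
                              qualLocation = c(tp = 90, fp = 28, fn = 60,
                                               nac = 30, o = 60, i = 60),
                              qualScale = 2, seed = 91),
                  dir = d)
  dWeak <- tempfile()
  generateFixture(fixtureSpec(tp = 60, fp = 25, nac = 15,
                              qualLocation = 60, qualScale = 10, seed = 91),
                  dir = dWeak)
  out <- tempfile()
  res <- runRocReport(file.path(d, "truth.vcf"),
                      c(strong = file.path(d, "query.vcf"),
                        weak = file.path(dWeak, "query.vcf")),
                      file.path(d, "target.bed"),
                      file.path(d, "confident.bed"),
                      outdir = out, quiet = TRUE)
  tab <- res$aucTable
  expect_equal(tab$auc[tab$caller == "strong"], 1)   # planted separation
  expect_equal(tab$p_printed[tab$caller == "strong"], "0.000")
  expect_lt(tab$auc[tab$caller == "weak"], 1)
  expect_gt(tab$auc[tab$caller == "strong"], tab$auc[tab$caller == "weak"])
  expect_true(file.exists(file.path(out, "roc_strong.tsv")))
  expect_true(file.exists(file.path(out, "roc.json")))
  expect_equal(nrow(res$pairwise), 1)

  # identical duplicated caller -> p = 1
  res2 <- runRocReport(file.path(d, "truth.vcf"),
                       c(a = file.path(d, "query.vcf"),
                         b = file.path(d, "query.vcf")),
                       file.path(d, "target.bed"),
                       file.path(d, "confident.bed"), quiet = TRUE)
  expect_equal(res2$pairwise$p, 1)
})
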