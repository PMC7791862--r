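# VCF/BED I/O, quality filtering and key normalization.

test_that("readVariants maps VCF fields, samples and annotations", {
  f <- minimalVcf(c(
    "1\t1014143\t.\tC\tT\t216\tPASS\tDP=30\tGT:DP\t0/1:30",
    "chr2\t50\trs1\tg\ta,t\t.\tPASS\tDP=12\tGT:DP\t1/2:12",
    paste0("2\t99\t.\tA\tG\t55\tPASS\t",
           "DP=40;ANN=G|missense_variant|MODERATE|MYH7|ENSG1|transcript|NM_1,",
           "G|missense_variant|MODERATE|MYH7|ENSG1|transcript|NM_2\t",
           "GT:DP\t0/1:41")
  ), withSample = TRUE)
  r <- readVariants(f)
  expect_equal(nrow(r), 3)
  expect_equal(r$pos[1], 1014143)
  expect_equal(r$qual[1], 216)
  expect_equal(r$depth[1], 30)     # FORMAT DP preferred
  expect_equal(r$alt[2], "A,T")    # multiallelic kept on one record
  expect_equal(r$ref[2], "G")      # alleles upper-cased
  expect_true(is.na(r$qual[2]))
  expect_equal(r$depth[3], 41)
  eff <- r$effects[[3]]
  expect_equal(nrow(eff), 2)       # transcript-level entries
  expect_equal(eff$gene, c("MYH7", "MYH7"))
  expect_equal(eff$transcript, c("NM_1", "NM_2"))
  expect_equal(unique(eff$effect), "missense_variant")
})

test_that("readVariants handles header-only files, INFO DP fallback and multi-sample files", {
  expect_equal(nrow(readVariants(minimalVcf())), 0)

  noFormat <- minimalVcf("1\t5\t.\tA\tG\t30\tPASS\tDP=22")
  expect_equal(readVariants(noFormat)$depth, 22L)

  two <- writeTempVcf(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "1\t5\t.\tA\tG\t30\tPASS\t.\tGT:DP\t0/1:9\t0/1:33"
  ))
  expect_error(readVariants(two), "specify")
  expect_equal(readVariants(two, sample = "S2")$depth, 33L)
  expect_error(readVariants(two, sample = "nope"), "not found")
})

test_that("malformed VCF data lines are reported with their line number", {
  bad <- minimalVcf("1\tnot_a_pos\t.\tA\tG\t30\tPASS\tDP=22")
  expect_error(readVariants(bad), "line 6")
  expect_error(readVariants(tempfile()), "no such VCF")
})

test_that("quality filters use strict inequalities and drop missing values", {
  r <- keysToRecords(makeKeys("1", 1:6, "A", "G"),
                     qual = c(20, 216, 19, 21, NA, 50),
                     depth = c(30, 11, 50, 50, 50, NA))
  kept <- applyQualityFilters(r)
  # qual=20 at boundary dropped; qual=216/depth=11 kept; NA qual/depth dropped
  expect_equal(kept$pos, c(2L, 4L))

  quals <- keysToRecords(makeKeys("1", 1:3, "A", "G"),
                         qual = c(19, 20, 21), depth = 50)
  expect_equal(applyQualityFilters(quals)$qual, 21)
})

test_that("raising filter thresholds never increases the surviving count", {
  set.seed(42)
  r <- keysToRecords(makeKeys("1", 1:200, "A", "G"),
                     qual = runif(200, 0, 60),
                     depth = sample.int(40, 200, replace = TRUE))
  prev <- nrow(r)
  for (mq in seq(0, 60, by = 5)) {
    n <- nrow(applyQualityFilters(r, minQual = mq, minDepth = 10))
    expect_lte(n, prev)
    prev <- n
  }
  prev <- nrow(r)
  for (md in seq(0, 40, by = 4)) {
    n <- nrow(applyQualityFilters(r, minQual = 0, minDepth = md))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("toKeys splits multiallelics, filters SNPs and normalizes dialects", {
  rec <- data.frame(chrom = "1", pos = 100L, id = NA, ref = "C", alt = "T,G",
                    qual = 50, filter = "PASS", depth = 30L, gt = "1/2",
                    effects = I(list(data.frame())), stringsAsFactors = FALSE)
  expect_equal(toKeys(rec), c("1:100:C:T", "1:100:C:G"))

  indel <- keysToRecords("1:100:CT:C")
  expect_equal(toKeys(indel), character())               # indel excluded
  expect_equal(toKeys(indel, snpOnly = FALSE), "1:100:CT:C")

  symbolic <- data.frame(chrom = "1", pos = 7L, id = NA, ref = "A",
                         alt = "<DEL>,A,*", qual = 1, filter = ".",
                         depth = 1L, gt = NA, effects = I(list(data.frame())),
                         stringsAsFactors = FALSE)
  expect_equal(toKeys(symbolic), character())  # symbolic and alt==ref dropped

  # key determinism across chr prefix and allele case
  a <- keysToRecords("1:100:C:T")
  b <- a; b$chrom <- "chr1"; b$ref <- "c"; b$alt <- "t"
  expect_identical(toKeys(a), toKeys(b))
})

test_that("genotype-aware keys require matching unordered genotypes", {
  het <- keysToRecords("1:100:C:T", gt = "0/1")
  hetFlip <- keysToRecords("1:100:C:T", gt = "1/0")
  hom <- keysToRecords("1:100:C:T", gt = "1/1")
  expect_identical(toKeys(het, genotype = TRUE), toKeys(hetFlip, genotype = TRUE))
  expect_false(identical(toKeys(het, genotype = TRUE),
                         toKeys(hom, genotype = TRUE)))
})

test_that("VCF write/read round-trips keys in identical order", {
  set.seed(7)
  tab <- randomKeyTable(40)
  tab <- tab[!duplicated(paste(tab$chrom, tab$pos)), ]
  keys <- makeKeys(tab$chrom, tab$pos, tab$ref, tab$alt)
  keys <- sortKeys(keys)
  rec <- keysToRecords(keys, qual = c(NA, round(runif(length(keys) - 1) * 100, 1)),
                       depth = 25L, gt = "0/1")
  f <- tempfile(fileext = ".vcf")
  writeVariantsVcf(rec, f)
  back <- readVariants(f)
  expect_identical(toKeys(back), keys)
  expect_true(is.na(back$qual[1]))                   # "." QUAL round-trip
  expect_equal(back$qual[-1], rec$qual[-1])
  expect_equal(back$depth, rec$depth)

  # empty collection -> valid header-only VCF
  f2 <- tempfile(fileext = ".vcf")
  writeVariantsVcf(character(), f2)
  expect_equal(nrow(readVariants(f2)), 0)
})

test_that("readBed merges, normalizes and reports malformed lines", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("1\t0\t10", "1\t5\t20"), f)
  r <- readBed(f)
  expect_equal(as.data.frame(r),
               data.frame(chrom = "1", start = 0, end = 20))
  expect_equal(totalLength(r), 20)

  writeLines(character(), f)
  expect_equal(length(readBed(f)), 0)

  writeLines("chr2\t100\t200", f)
  r <- readBed(f)
  expect_equal(as.data.frame(r)$chrom, "2")
  expect_equal(totalLength(r), 100)

  writeLines(c("track name=x", "1\t10\t5"), f)
  expect_error(readBed(f), "line 2")
  writeLines(c("1\t0\t10", "1\t-5\t10"), f)
  expect_error(readBed(f), "line 2")
})

test_that("BED round-trips through writeBed", {
  set.seed(11)
  rs <- RegionSet(rep("1", 20), (0:19) * 100, (0:19) * 100 + sample.int(80, 20))
  f <- tempfile(fileext = ".bed")
  writeBed(rs, f)
  expect_equal(as.data.frame(readBed(f)), as.data.frame(rs))
})
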