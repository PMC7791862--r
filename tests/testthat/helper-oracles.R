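# Independent brute-force oracles and small input builders used across
# the suite. The oracles deliberately avoid the package's interval and
# set machinery: membership is decided by scanning raw interval tables,
# set categories by enumerating membership signatures, AUC by counting
# all positive-negative pairs.

# ---- input builders ----------------------------------------------------

writeTempVcf <- function(lines, ext = ".vcf") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

minimalVcf <- function(dataLines = character(), withSample = FALSE,
                       samples = "S1") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">"
  )
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (withSample) cols <- c(cols, "FORMAT", samples)
  writeTempVcf(c(header, paste(cols, collapse = "\t"), dataLines))
}

randomKeyTable <- function(n, chroms = c("1", "2"), maxPos = 10000) {
  pos <- sample.int(maxPos, n, replace = TRUE)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  data.frame(chrom = sample(chroms, n, replace = TRUE), pos = pos,
             ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
}

randomIntervals <- function(n, chroms = "1", maxLen = 10000) {
  start <- sample.int(maxLen - 1, n, replace = TRUE) - 1
  width <- sample.int(50, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = pmin(start + width, maxLen),
             stringsAsFactors = FALSE)
}

# ---- oracles -----------------------------------------------------------

# Per-base bitmap of covered 0-based positions, as "chrom:base" strings.
oracleCoveredBases <- function(df) {
  if (nrow(df) == 0) return(character())
  unique(unlist(lapply(seq_len(nrow(df)), function(j) {
    if (df$end[j] <= df$start[j]) return(character())
    paste(df$chrom[j], seq.int(df$start[j], df$end[j] - 1), sep = ":")
  })))
}

# Membership of 1-based positions in a raw interval table (linear scan).
oracleContains <- function(df, chrom, pos) {
  vapply(seq_along(pos), function(k) {
    any(df$chrom == chrom[k] & df$start <= pos[k] - 1 & pos[k] - 1 < df$end)
  }, TRUE)
}

# The six categories by explicit membership-signature enumeration.
oracleCategories <- function(A, B, C) {
  u <- unique(c(A, B, C))
  inA <- u %in% A; inB <- u %in% B; inC <- u %in% C
  list(
    tp  = u[inA & inB],
    fp  = u[inB & inC & !inA],
    fn  = u[inA & inC & !inB],
    nac = u[inB & !inA & !inC],
    o   = u[inC & !inA & !inB],
    i   = u[inA & !inB & !inC]
  )
}

# Venn cell tally by per-element signature.
oracleVennCells <- function(callsets) {
  nm <- names(callsets)
  u <- unique(unlist(callsets, use.names = FALSE))
  sig <- vapply(u, function(k)
    paste(nm[vapply(callsets, function(s) k %in% s, TRUE)], collapse = "&"), "")
  table(sig)
}

# Rank AUC by O(n^2) pair counting, ties half credit.
oracleAuc <- function(score, label) {
  x <- score[label]; y <- score[!label]
  s <- 0
  for (xi in x) s <- s + sum(xi > y) + 0.5 * sum(xi == y)
  s / (length(x) * length(y))
}

# Draw a random satisfiable fixture spec (fn = 0 always: the FN category
# is structurally empty, see generateFixture).
randomFixtureSpec <- function(seed) {
  set.seed(seed)
  fixtureSpec(
    tp = sample(0:40, 1), fp = sample(0:10, 1), fn = 0,
    nac = sample(0:10, 1), o = sample(0:10, 1), i = sample(0:5, 1),
    decoys = sample(0:5, 1),
    nChroms = sample(1:3, 1), chromLength = 5000,
    targetFraction = runif(1, 0.3, 0.8),
    confidentFraction = runif(1, 0.3, 0.8),
    seed = seed
  )
}

# Run the full pipeline on an in-memory bundle and return DiscreteCounts.
recoverCounts <- function(bundle, minQual = 20, minDepth = 10) {
  q <- applyQualityFilters(bundle$query, minQual = minQual, minDepth = minDepth)
  computeDiscrete(buildSets(toKeys(bundle$truth), toKeys(q),
                            bundle$target, bundle$confident))
}
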