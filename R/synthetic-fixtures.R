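# Synthetic benchmark fixtures: complete input bundles (truth VCF, query
# VCF, target BED, confident BED) with exactly controlled category
# counts, fully reproducible from a seed.
#
# Geometry: each synthetic chromosome is laid out as four consecutive
# zones classified by target/confident membership,
#   [0, TC)                target & confident
#   [TC, T)                target only
#   [T, T + Conly)         confident only
#   [T + Conly, L)         neither,
# so every membership signature needed by the categories has room:
# tp/fp live in the target&confident zone, nac/i in target-only, o in
# confident-only. Positions are drawn without replacement (one variant
# per base) so planted keys never collide.
#
# fn is structurally unplantable: FN = (A intersect C) \ B, and because B
# and C derive from the same query call set, any key in A and C is in
# query and target, hence in B — FN is empty for every input. A truth
# variant the caller misses lands in I instead (and requesting fn > 0 is
# reported as unsatisfiable).

#' Describe a synthetic benchmark fixture
#'
#' @param tp,fp,fn,nac,o,i requested category counts (non-negative).
#'   `fn` must be 0: the category FN = (A intersect C) \\ B is empty for
#'   every possible input because B and C derive from the same query
#'   call set, so no placement can produce it (see [generateFixture()]).
#' @param decoys number of sub-threshold query calls (QUAL <= 20 or
#'   DP <= 10) planted in addition; they must vanish under the default
#'   filters and appear in no category.
#' @param nChroms number of synthetic chromosomes (named "1", "2", ...).
#' @param chromLength length of each chromosome in bases.
#' @param targetFraction fraction of each chromosome covered by the
#'   target regions (0 < f <= 1).
#' @param confidentFraction fraction of the target (and of the
#'   off-target remainder) covered by confident regions (0 < f <= 1).
#' @param qualLocation,qualScale per-category location/scale of the
#'   planted QUAL values (named vectors over tp, fp, fn, nac, o, i are
#'   accepted; scalars are recycled). Draws are clipped to pass the
#'   default QUAL > 20 filter.
#' @param depthRange inclusive integer range of planted DP values; the
#'   default (20, 100) passes the default DP > 10 filter.
#' @param tsBias probability that a planted substitution is a transition
#'   (A<->G, C<->T); 0.7 approximates the genome-wide excess of
#'   transitions.
#' @param seed integer seed; identical spec + seed gives byte-identical
#'   output files.
#' @return an object of class `fixture_spec`.
#' @export
fixtureSpec <- function(tp = 0, fp = 0, fn = 0, nac = 0, o = 0, i = 0,
                        decoys = 0, nChroms = 1, chromLength = 1e6,
                        targetFraction = 0.5, confidentFraction = 0.5,
                        qualLocation = 60, qualScale = 10,
                        depthRange = c(20, 100), tsBias = 0.7, seed = 1) {
  counts <- c(tp = tp, fp = fp, fn = fn, nac = nac, o = o, i = i)
  stopifnot(all(counts >= 0), decoys >= 0, nChroms >= 1, chromLength >= 8,
            targetFraction > 0, targetFraction <= 1,
            confidentFraction > 0, confidentFraction <= 1,
            length(depthRange) == 2, depthRange[1] <= depthRange[2],
            tsBias >= 0, tsBias <= 1)
  full <- function(v) {
    v <- if (length(v) == 1) rep(v, 6) else v
    stopifnot(length(v) == 6)
    if (is.null(names(v))) names(v) <- names(counts)
    v[names(counts)]
  }
  structure(list(
    counts = setNames(as.integer(counts), names(counts)),
    decoys = as.integer(decoys),
    nChroms = as.integer(nChroms), chromLength = as.integer(chromLength),
    targetFraction = targetFraction, confidentFraction = confidentFraction,
    qualLocation = full(qualLocation), qualScale = full(qualScale),
    depthRange = as.integer(depthRange), tsBias = tsBias,
    seed = as.integer(seed)
  ), class = "fixture_spec")
}

# Zone layout for one chromosome; all coordinates 0-based half-open.
.zones <- function(spec) {
  L <- spec$chromLength
  tLen <- max(1, floor(L * spec$targetFraction))
  tc <- max(1, floor(tLen * spec$confidentFraction))
  rest <- L - tLen
  conly <- floor(rest * spec$confidentFraction)
  list(tc = c(0, tc), tonly = c(tc, tLen),
       conly = c(tLen, tLen + conly),
       target = c(0, tLen),
       confident = rbind(c(0, tc),
                         if (conly > 0) c(tLen, tLen + conly)))
}

.zoneCapacity <- function(z) {
  vapply(z[c("tc", "tonly", "conly")],
         function(iv) max(0, iv[2] - iv[1]), 0)
}

#' Generate a synthetic benchmark bundle
#'
#' Plants each requested variant so that its membership signature (in
#' truth? called? in target? in confident?) yields exactly the requested
#' category:
#' \itemize{
#'   \item tp: truth + query, target & confident zone
#'   \item fp: query only, target & confident zone
#'   \item nac: query only, target-only zone
#'   \item o: query only, confident-only zone
#'   \item i: truth only, target-only zone
#' }
#' `fn > 0` is rejected as unsatisfiable: FN = (A intersect C) \\ B is
#' empty for every input, since a key in A and C is in the query and in
#' the target regions and therefore in B.
#' A single RNG stream is seeded once and consumed in fixed order
#' (positions per zone, then alleles, then QUAL/DP, then decoys), so the
#' bundle is reproducible and adding decoys does not shift earlier draws.
#'
#' @param spec a [fixtureSpec()] object.
#' @param dir optional directory; when given, `truth.vcf`, `query.vcf`,
#'   `target.bed`, `confident.bed` and `manifest.json` are written there.
#' @return a list of class `fixture_bundle` with elements `truth` and
#'   `query` (record data.frames), `target` and `confident`
#'   ([RegionSet-class]), `expected` (named category counts), `spec`,
#'   and `paths` when `dir` was given.
#' @examples
#' b <- generateFixture(fixtureSpec(tp = 5, fp = 1, nac = 2, seed = 42))
#' categoryCounts(computeDiscrete(buildSets(toKeys(b$truth),
#'   toKeys(applyQualityFilters(b$query)), b$target, b$confident)))
#' @export
generateFixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  ct <- setNames(as.numeric(spec$counts), names(.catZone()))
  if (ct[["fn"]] > 0)
    stop("unsatisfiable fixture spec: the fn class is impossible. ",
         "FN = (A ∩ C) \\ B is empty for every input because B and C ",
         "derive from the same query call set: a key in A and C is in ",
         "the query and in target regions, hence in B. A truth variant ",
         "the caller misses belongs to I (plant it via `i`).")
  z <- .zones(spec)
  cap <- .zoneCapacity(z) * spec$nChroms
  need <- c(tc = ct[["tp"]] + ct[["fp"]] + spec$decoys,
            tonly = ct[["nac"]] + ct[["i"]],
            conly = ct[["o"]])
  for (zn in names(need)) {
    if (need[[zn]] > cap[[zn]]) {
      blame <- names(.catZone())[.catZone() == zn]
      stop("unsatisfiable fixture spec: zone '", zn, "' (",
           paste(blame, collapse = "/"), if (zn == "tc") " and decoys" else "",
           ") offers ", cap[[zn]], " positions but ", need[[zn]],
           " are requested; enlarge chromLength or adjust ",
           "targetFraction/confidentFraction")
    }
  }

  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(spec$seed)

  chroms <- as.character(seq_len(spec$nChroms))
  # 1) positions: draw per zone, without replacement, across chromosomes
  drawZone <- function(zone, n) {
    if (n == 0) return(data.frame(chrom = character(), pos = integer()))
    perChrom <- zone[2] - zone[1]
    pool <- data.frame(
      chrom = rep(chroms, each = perChrom),
      pos = rep(seq.int(zone[1] + 1, zone[2]), times = spec$nChroms)
    )
    pool[sample.int(nrow(pool), n), , drop = FALSE]
  }
  posTC <- drawZone(z$tc, need[["tc"]])
  posT <- drawZone(z$tonly, need[["tonly"]])
  posC <- drawZone(z$conly, need[["conly"]])

  assign6 <- rbind(
    .take(posTC, ct[["tp"]], 0), .take(posTC, ct[["fp"]], ct[["tp"]]),
    .take(posT, ct[["nac"]], 0), .take(posT, ct[["i"]], ct[["nac"]]),
    .take(posC, ct[["o"]], 0)
  )
  assign6$category <- rep(c("tp", "fp", "nac", "i", "o"),
                          times = c(ct[["tp"]], ct[["fp"]],
                                    ct[["nac"]], ct[["i"]], ct[["o"]]))
  decoyPos <- .take(posTC, spec$decoys, ct[["tp"]] + ct[["fp"]])

  # 2) alleles
  nv <- nrow(assign6)
  alle <- .drawAlleles(nv + nrow(decoyPos), spec$tsBias)
  assign6$ref <- alle$ref[seq_len(nv)]
  assign6$alt <- alle$alt[seq_len(nv)]
  if (nrow(decoyPos) > 0) {
    decoyPos$ref <- alle$ref[nv + seq_len(nrow(decoyPos))]
    decoyPos$alt <- alle$alt[nv + seq_len(nrow(decoyPos))]
  }

  # 3) QUAL/DP per planted variant (query side); truth gets fixed values
  loc <- spec$qualLocation[assign6$category]
  sca <- spec$qualScale[assign6$category]
  assign6$qual <- pmax(20.5, round(loc + sca * rnorm(nv), 1))
  assign6$depth <- sample.int(spec$depthRange[2] - spec$depthRange[1] + 1L,
                              nv, replace = TRUE) + spec$depthRange[1] - 1L

  # 4) decoys: alternate failing QUAL and failing DP
  if (nrow(decoyPos) > 0) {
    k <- seq_len(nrow(decoyPos))
    failQual <- k %% 2 == 1
    decoyPos$qual <- ifelse(failQual, round(runif(nrow(decoyPos)) * 19, 1),
                            pmax(20.5, round(60 + 10 * rnorm(nrow(decoyPos)), 1)))
    decoyPos$depth <- ifelse(failQual,
                             sample.int(50, nrow(decoyPos), replace = TRUE) + 19L,
                             sample.int(10, nrow(decoyPos), replace = TRUE) - 1L)
    decoyPos$category <- "decoy"
  }

  inTruth <- assign6$category %in% c("tp", "i")
  inQuery <- assign6$category %in% c("tp", "fp", "nac", "o")
  truthDf <- assign6[inTruth, , drop = FALSE]
  queryDf <- rbind(assign6[inQuery, , drop = FALSE], decoyPos)

  orderDf <- function(d) d[order(.chromRank(d$chrom), d$pos), , drop = FALSE]
  truthDf <- orderDf(truthDf); queryDf <- orderDf(queryDf)

  truth <- keysToRecords(makeKeys(truthDf$chrom, truthDf$pos,
                                  truthDf$ref, truthDf$alt),
                         qual = 100, depth = 50, gt = "0/1")
  query <- keysToRecords(makeKeys(queryDf$chrom, queryDf$pos,
                                  queryDf$ref, queryDf$alt),
                         qual = queryDf$qual, depth = queryDf$depth,
                         gt = "0/1")

  target <- RegionSet(chroms, rep(z$target[1], length(chroms)),
                      rep(z$target[2], length(chroms)))
  conf <- do.call(rbind, lapply(chroms, function(ch)
    data.frame(chrom = ch, start = z$confident[, 1], end = z$confident[, 2])))
  confident <- RegionSet(conf$chrom, conf$start, conf$end)

  expected <- setNames(spec$counts, c("tp", "fp", "fn", "nac", "o", "i"))
  bundle <- structure(list(truth = truth, query = query, target = target,
                           confident = confident, expected = expected,
                           spec = spec),
                      class = "fixture_bundle")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(truth = file.path(dir, "truth.vcf"),
                  query = file.path(dir, "query.vcf"),
                  target = file.path(dir, "target.bed"),
                  confident = file.path(dir, "confident.bed"),
                  manifest = file.path(dir, "manifest.json"))
    writeVariantsVcf(truth, paths$truth)
    writeVariantsVcf(query, paths$query)
    writeBed(target, paths$target)
    writeBed(confident, paths$confident)
    jsonlite::write_json(
      list(spec = unclass(spec), expected = as.list(expected)),
      paths$manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    bundle$paths <- paths
  }
  bundle
}

.catZone <- function() c(tp = "tc", fp = "tc", fn = "tc",
                         nac = "tonly", o = "conly", i = "tonly")

.take <- function(df, n, offset) df[offset + seq_len(n), , drop = FALSE]

.TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
.TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                     C = c("A", "G"), T = c("A", "G"))

.drawAlleles <- function(n, tsBias) {
  if (n == 0) return(list(ref = character(), alt = character()))
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  isTs <- runif(n) < tsBias
  pick <- runif(n) < 0.5
  alt <- ifelse(isTs, .TS_PARTNER[ref],
                mapply(function(r, p) .TV_PARTNERS[[r]][1 + p], ref, pick))
  list(ref = ref, alt = unname(alt))
}

.saveSeed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restoreSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate three query call sets with planted Venn concordance
#'
#' Plants a three-caller concordance structure: every cell of the
#' three-set Venn partition receives exactly the requested number of
#' variant keys, so [concordance()] on the result recovers the cells
#' exactly.
#'
#' @param cells named integer vector over the 7 Venn cells; names are
#'   caller names joined by "&" (e.g. `c(freebayes = 2, "freebayes&isaac"
#'   = 1, "freebayes&isaac&varscan" = 251)`). Missing cells default to 0.
#' @param callers the three caller names.
#' @param nChroms,chromLength,tsBias,seed as in [fixtureSpec()].
#' @return list of class `fixture_trio`: `callsets` (named list of three
#'   key vectors), `expectedCells` (data.frame as in [concordance()]),
#'   and `truth` (the keys shared by all three callers, usable as a
#'   common truth set).
#' @export
generateTrio <- function(cells, callers = c("caller1", "caller2", "caller3"),
                         nChroms = 1, chromLength = 1e6, tsBias = 0.7,
                         seed = 1) {
  stopifnot(length(callers) == 3, !anyDuplicated(callers))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 3))[-1, , drop = FALSE]
  names(combos) <- callers
  lab <- apply(combos, 1, function(r) paste(callers[as.logical(r)], collapse = "&"))
  want <- setNames(integer(length(lab)), lab)
  if (!all(names(cells) %in% lab))
    stop("unknown cell name(s): ",
         paste(setdiff(names(cells), lab), collapse = ", "),
         " (valid: ", paste(lab, collapse = ", "), ")")
  want[names(cells)] <- as.integer(cells)
  total <- sum(want)
  if (total > nChroms * chromLength)
    stop("unsatisfiable trio: ", total, " keys requested but only ",
         nChroms * chromLength, " positions available")

  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(seed)
  chroms <- as.character(seq_len(nChroms))
  pool <- data.frame(chrom = rep(chroms, each = chromLength),
                     pos = rep(seq_len(chromLength), times = nChroms))
  pos <- pool[sample.int(nrow(pool), total), , drop = FALSE]
  alle <- .drawAlleles(total, tsBias)
  keys <- makeKeys(pos$chrom, pos$pos, alle$ref, alle$alt)

  cellOf <- rep(seq_along(lab), times = want)
  callsets <- lapply(seq_along(callers), function(ci) {
    inCell <- which(as.matrix(combos)[cellOf, ci])
    sortKeys(keys[inCell])
  })
  names(callsets) <- callers
  structure(list(
    callsets = callsets,
    expectedCells = data.frame(sets = lab, count = as.integer(want),
                               row.names = NULL, stringsAsFactors = FALSE),
    truth = sortKeys(keys[cellOf == which(lab == paste(callers, collapse = "&"))])
  ), class = "fixture_trio")
}
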