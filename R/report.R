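# Orchestration and reporting: end-to-end benchmark runs over VCF/BED
# inputs, ROC reports, and the fixture-simulation entry point used by
# the command-line wrapper (inst/scripts/vcbench.R).

#' Run the full set-theory benchmark
#'
#' Reads the truth VCF, one or more query VCFs, the target BED and the
#' high-confidence BED; filters the query calls (QUAL/DP, strict
#' inequalities); builds sets A, B, C per caller; derives the six
#' discrete categories and the continuous metrics; computes the region
#' intersection summary and (for >= 2 callers) the Venn concordance.
#' When `outdir` is given, writes per-caller category VCFs (tp.vcf,
#' fp.vcf, fn.vcf, nac.vcf, o.vcf, i.vcf), a metrics table (TSV + JSON),
#' a Venn cell table (TSV), a region summary and a run manifest (JSON).
#' Every number in the TSV is re-derivable from the category VCFs
#' written alongside it.
#'
#' @param truthVcf path to the gold-standard VCF (used unfiltered).
#' @param queryVcfs named character vector of query VCF paths (names are
#'   the caller labels; unnamed single paths get the label "query").
#' @param targetBed,confidentBed paths to the BED files.
#' @param outdir optional output directory.
#' @param minQual,minDepth query filter thresholds (strict; defaults
#'   QUAL > 20, DP > 10).
#' @param snpOnly restrict to single-base substitutions.
#' @param genotypeMatch require identical unordered genotypes for a
#'   match, in addition to position and alleles.
#' @param truthSample,querySample sample names passed to
#'   [readVariants()] when files carry several samples.
#' @param quiet suppress INFO logging (set sizes, region lengths).
#' @return invisibly, a list with `metrics` (data.frame, one row per
#'   caller in TP/FP/FN/I/NAC/Recall/Precision/Frac_NA/F1 order),
#'   `discrete` (named list of [DiscreteCounts-class]), `sets` (named
#'   list of [BenchmarkSets-class]), `regions` (lengths and overlap
#'   percentage), and `concordance` (when >= 2 callers).
#' @export
runBenchmark <- function(truthVcf, queryVcfs, targetBed, confidentBed,
                         outdir = NULL, minQual = 20, minDepth = 10,
                         snpOnly = TRUE, genotypeMatch = FALSE,
                         truthSample = NULL, querySample = NULL,
                         quiet = FALSE) {
  if (is.null(names(queryVcfs)))
    names(queryVcfs) <- if (length(queryVcfs) == 1) "query" else
      paste0("query", seq_along(queryVcfs))
  say <- function(...) if (!quiet) message("INFO: ", ...)

  target <- readBed(targetBed)
  confident <- readBed(confidentBed)
  overlap <- intersect(target, confident)
  regions <- list(
    target_bp = totalLength(target),
    confident_bp = totalLength(confident),
    overlap_bp = totalLength(overlap),
    overlap_pct = if (totalLength(target) > 0)
      100 * totalLength(overlap) / totalLength(target) else NA_real_
  )
  fmt <- function(x) format(x, big.mark = ",", scientific = FALSE)
  say(sprintf("target %s bp, confident %s bp, intersection %s bp (%.1f%% of target)",
              fmt(regions$target_bp), fmt(regions$confident_bp),
              fmt(regions$overlap_bp), regions$overlap_pct))
  if (totalLength(confident) == 0)
    warning("empty high-confidence region set: C will be empty and ",
            "FP/FN/O are zero by construction; only NAC/I are informative")

  truthRec <- readVariants(truthVcf, sample = truthSample)
  truthKeys <- toKeys(truthRec, snpOnly = snpOnly, genotype = genotypeMatch)

  sets <- list(); discrete <- list(); callKeys <- list()
  metrics <- NULL
  for (caller in names(queryVcfs)) {
    rec <- readVariants(queryVcfs[[caller]], sample = querySample)
    rec <- applyQualityFilters(rec, minQual = minQual, minDepth = minDepth)
    keys <- toKeys(rec, snpOnly = snpOnly, genotype = genotypeMatch)
    bs <- buildSets(truthKeys, keys, target, confident)
    dc <- computeDiscrete(bs)
    say(sprintf("%s: |A| = %d, |B| = %d, |C| = %d", caller,
                length(bs@A), length(bs@B), length(bs@C)))
    sets[[caller]] <- bs
    discrete[[caller]] <- dc
    callKeys[[caller]] <- bs@B
    metrics <- rbind(metrics, metricsRow(dc, caller = caller))
  }

  venn <- if (length(queryVcfs) >= 2) concordance(callKeys) else NULL

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (caller in names(discrete)) {
      cdir <- file.path(outdir, caller)
      dir.create(cdir, showWarnings = FALSE)
      for (cat in names(discrete[[caller]]@members))
        writeVariantsVcf(discrete[[caller]]@members[[cat]],
                         file.path(cdir, paste0(cat, ".vcf")))
    }
    utils::write.table(metrics, file.path(outdir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    jsonlite::write_json(
      list(metrics = metrics, regions = regions,
           settings = list(min_qual = minQual, min_depth = minDepth,
                           snp_only = snpOnly,
                           genotype_match = genotypeMatch)),
      file.path(outdir, "metrics.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "string")
    if (!is.null(venn))
      utils::write.table(venn$cells, file.path(outdir, "concordance.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(regions, file.path(outdir, "region_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  invisible(list(metrics = metrics, discrete = discrete, sets = sets,
                 regions = regions, concordance = venn))
}

#' ROC report across callers
#'
#' Builds scored calls per caller (label: the call is in the truth set A;
#' score: the call's QUAL), fits the ROC curve, tests each AUC against
#' chance and compares all caller pairs at the 95% significance level.
#'
#' @inheritParams runBenchmark
#' @param paired use the paired (DeLong, shared keys) comparison instead
#'   of the unpaired Hanley-McNeil z-test.
#' @return invisibly, a list with `roc` (named list of
#'   [RocResult-class]), `aucTable` (data.frame: caller, auc, se, z, p)
#'   and `pairwise` (data.frame: callerA, callerB, z, p). When `outdir`
#'   is given, writes per-caller ROC points (TSV) and `roc.json`
#'   (p-values below 5e-4 are printed "0.000" in the tables; exact
#'   values are kept in the JSON).
#' @export
runRocReport <- function(truthVcf, queryVcfs, targetBed, confidentBed,
                         outdir = NULL, minQual = 20, minDepth = 10,
                         snpOnly = TRUE, paired = FALSE,
                         truthSample = NULL, querySample = NULL,
                         quiet = FALSE) {
  if (is.null(names(queryVcfs)))
    names(queryVcfs) <- if (length(queryVcfs) == 1) "query" else
      paste0("query", seq_along(queryVcfs))
  target <- readBed(targetBed)
  confident <- readBed(confidentBed)
  truthRec <- readVariants(truthVcf, sample = truthSample)
  truthKeys <- toKeys(truthRec, snpOnly = snpOnly)

  roc <- list()
  for (caller in names(queryVcfs)) {
    rec <- readVariants(queryVcfs[[caller]], sample = querySample)
    rec <- applyQualityFilters(rec, minQual = minQual, minDepth = minDepth)
    keys <- toKeys(rec, snpOnly = snpOnly)
    bs <- buildSets(truthKeys, keys, target, confident)
    roc[[caller]] <- rocCurve(scoredCalls(rec, bs, snpOnly = snpOnly))
  }

  aucTable <- do.call(rbind, lapply(names(roc), function(cl) {
    r <- roc[[cl]]
    data.frame(caller = cl, auc = r@auc, se = r@se, z = r@z, p = r@p,
               p_printed = formatPValue(r@p), stringsAsFactors = FALSE)
  }))

  pairwise <- NULL
  nm <- names(roc)
  if (length(nm) >= 2) {
    for (a in seq_len(length(nm) - 1)) for (b in seq((a + 1), length(nm))) {
      zp <- compareAuc(roc[[nm[a]]], roc[[nm[b]]], paired = paired)
      pairwise <- rbind(pairwise, data.frame(
        callerA = nm[a], callerB = nm[b], z = zp[["z"]], p = zp[["p"]],
        p_printed = formatPValue(zp[["p"]]),
        significant_at_95 = !is.na(zp[["p"]]) && zp[["p"]] < 0.05,
        stringsAsFactors = FALSE))
    }
  }

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (cl in names(roc))
      utils::write.table(rocPoints(roc[[cl]]),
                         file.path(outdir, paste0("roc_", cl, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(auc = aucTable, pairwise = pairwise,
           scoring = list(label = "call in truth set A among calls in B",
                          score = "QUAL")),
      file.path(outdir, "roc.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  invisible(list(roc = roc, aucTable = aucTable, pairwise = pairwise))
}

#' Simulate a benchmark fixture bundle on disk
#'
#' Thin wrapper over [generateFixture()] for the command line: writes
#' truth.vcf, query.vcf, target.bed, confident.bed and manifest.json.
#'
#' @param dir output directory.
#' @param ... passed to [fixtureSpec()].
#' @return the fixture bundle, invisibly.
#' @export
simulateFixture <- function(dir, ...) {
  invisible(generateFixture(fixtureSpec(...), dir = dir))
}
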