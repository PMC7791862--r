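# VCF and BED input/output, quality filtering, and normalization of
# variant records into comparable keys.

#' Read a VCF file into a variant record table
#'
#' Parses a VCF 4.x file (plain or gzip/bgzip compressed) into one row
#' per data line, in file order. Read depth (DP) is taken from the named
#' sample's FORMAT field when present, falling back to the INFO DP field.
#' SnpEff-style `ANN=` INFO annotations, when present, are parsed into a
#' per-record effects table (gene, transcript, effect).
#'
#' @param path path to a VCF file.
#' @param sample sample name whose FORMAT fields (DP, GT) are used.
#'   Mandatory when the file carries more than one sample column.
#' @return a data.frame with columns `chrom`, `pos`, `id`, `ref`, `alt`
#'   (comma-joined as in the file), `qual`, `filter`, `depth`, `gt` and a
#'   list-column `effects` (each element a data.frame with columns
#'   `gene`, `transcript`, `effect`).
#' @examples
#' f <- tempfile(fileext = ".vcf")
#' writeVariantsVcf(keysToRecords(makeKeys("1", 1014143, "C", "T")), f)
#' readVariants(f)
#' @export
readVariants <- function(path, sample = NULL) {
  if (!file.exists(path)) stop("no such VCF file: ", path)
  v <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE)),
    error = function(e) stop("failed to parse VCF ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- v@fix
  n <- nrow(fix)
  headerLines <- length(v@meta) + 1L  # meta lines + #CHROM line
  if (n == 0) return(.emptyRecords())

  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1]
    stop("malformed VCF data line ", headerLines + bad, " in ", path,
         ": non-integer POS '", fix[bad, "POS"], "'")
  }
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  if (any(is.na(ref) | ref == "")) {
    bad <- which(is.na(ref) | ref == "")[1]
    stop("malformed VCF data line ", headerLines + bad, " in ", path,
         ": empty REF")
  }

  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  info <- fix[, "INFO"]

  # DP: sample FORMAT field first, INFO fallback
  depth <- rep(NA_integer_, n)
  if (!is.null(v@gt) && nrow(v@gt) == n && ncol(v@gt) >= 2) {
    samples <- colnames(v@gt)[-1]
    if (is.null(sample)) {
      if (length(samples) > 1)
        stop("VCF ", path, " has ", length(samples),
             " samples (", paste(samples, collapse = ", "),
             "); specify `sample`")
      sample <- samples[1]
    } else if (!sample %in% samples) {
      stop("sample '", sample, "' not found in ", path,
           " (has: ", paste(samples, collapse = ", "), ")")
    }
    gtmat <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                      error = function(e) NULL)
    if (!is.null(gtmat)) depth <- as.integer(gtmat[, sample])
    gt <- tryCatch(vcfR::extract.gt(v, element = "GT")[, sample],
                   error = function(e) rep(NA_character_, n))
  } else {
    gt <- rep(NA_character_, n)
  }
  infoDP <- suppressWarnings(as.integer(.infoField(info, "DP")))
  depth <- ifelse(is.na(depth), infoDP, depth)

  id <- fix[, "ID"]
  id[is.na(id) | id == "."] <- NA_character_

  data.frame(
    chrom = as.character(fix[, "CHROM"]),
    pos = pos,
    id = id,
    ref = ref,
    alt = alt,
    qual = qual,
    filter = as.character(fix[, "FILTER"]),
    depth = as.integer(depth),
    gt = unname(gt),
    effects = I(.parseAnn(info, alt)),
    stringsAsFactors = FALSE
  )
}

.emptyRecords <- function() {
  data.frame(chrom = character(), pos = integer(), id = character(),
             ref = character(), alt = character(), qual = numeric(),
             filter = character(), depth = integer(), gt = character(),
             effects = I(list()), stringsAsFactors = FALSE)
}

.emptyEffects <- function() {
  data.frame(gene = character(), transcript = character(),
             effect = character(), stringsAsFactors = FALSE)
}

# Extract "FIELD=value" from VCF INFO strings; NA where absent.
.infoField <- function(info, field) {
  info <- ifelse(is.na(info), "", info)
  pat <- paste0("(^|;)", field, "=([^;]*)")
  m <- regexpr(pat, info)
  out <- rep(NA_character_, length(info))
  hit <- !is.na(m) & m > 0
  out[hit] <- sub(pat, "\\2", regmatches(info, m))
  out
}

# Parse SnpEff ANN= entries: Allele|Annotation|Impact|Gene_Name|Gene_ID|
# Feature_Type|Feature_ID|...  ->  (gene, transcript, effect) triples.
.parseAnn <- function(info, alt) {
  annAll <- .infoField(info, "ANN")
  lapply(seq_along(info), function(j) {
    ann <- annAll[j]
    if (is.na(ann) || !nzchar(ann)) return(.emptyEffects())
    entries <- strsplit(ann, ",", fixed = TRUE)[[1]]
    fields <- strsplit(entries, "|", fixed = TRUE)
    data.frame(
      gene = vapply(fields, function(f) if (length(f) >= 4) f[4] else NA_character_, ""),
      transcript = vapply(fields, function(f) if (length(f) >= 7) f[7] else NA_character_, ""),
      effect = vapply(fields, function(f) if (length(f) >= 2) f[2] else NA_character_, ""),
      stringsAsFactors = FALSE
    )
  })
}

#' Filter variant records on call quality and read depth
#'
#' Keeps records with `qual` strictly greater than `minQual` and `depth`
#' strictly greater than `minDepth` (the defaults QUAL > 20, DP > 10 are
#' the usual post-calling hard filter for targeted panels). Records with
#' missing QUAL or DP fail the filter: a record that cannot demonstrate
#' its quality is treated conservatively.
#'
#' @param records data.frame from [readVariants()].
#' @param minQual,minDepth non-negative thresholds (strict inequalities).
#' @return the surviving records, original order preserved.
#' @examples
#' r <- keysToRecords(makeKeys("1", 1:3, "A", "G"),
#'                    qual = c(19, 20, 21), depth = c(50, 50, 50))
#' applyQualityFilters(r)  # only the qual = 21 record survives
#' @export
applyQualityFilters <- function(records, minQual = 20, minDepth = 10) {
  stopifnot(is.data.frame(records), minQual >= 0, minDepth >= 0)
  if (nrow(records) == 0) return(records)
  keep <- !is.na(records$qual) & !is.na(records$depth) &
    records$qual > minQual & records$depth > minDepth
  records[keep, , drop = FALSE]
}

#' Normalize variant records into comparable keys
#'
#' Produces one key per alternate allele (multiallelic records are
#' split), with the chromosome normalized and alleles upper-cased.
#' Symbolic alternate alleles (`<DEL>`, breakends, `*`) and alt == ref
#' entries are dropped. With `snpOnly = TRUE` (the default, matching the
#' SNP scope of the benchmark) only 1 bp -> 1 bp substitutions survive.
#' No indel left-alignment or trimming is performed: SNP keys are already
#' canonical, and indel comparison across representations is out of
#' scope.
#'
#' @param records data.frame from [readVariants()].
#' @param snpOnly drop keys whose ref or alt is not a single base.
#' @param genotype append the sample genotype (as a sorted allele-base
#'   pair) as a fifth key field, so matching also requires identical
#'   unordered genotypes.
#' @return character vector of keys in record order (duplicates, if any,
#'   are preserved here and removed at set construction).
#' @examples
#' toKeys(keysToRecords(makeKeys("chr1", 100, "C", "T")))
#' @export
toKeys <- function(records, snpOnly = TRUE, genotype = FALSE) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) return(character())
  alts <- strsplit(toupper(records$alt), ",", fixed = TRUE)
  nalt <- lengths(alts)
  idx <- rep(seq_len(nrow(records)), nalt)
  alt <- unlist(alts, use.names = FALSE)
  ref <- toupper(records$ref)[idx]
  chrom <- normalizeChrom(records$chrom)[idx]
  pos <- records$pos[idx]

  ok <- grepl("^[ACGTN]+$", alt) & grepl("^[ACGTN]+$", ref) & alt != ref
  if (snpOnly) ok <- ok & nchar(ref) == 1 & nchar(alt) == 1
  if (!any(ok)) return(character())

  gt <- NULL
  if (genotype) {
    gt <- vapply(seq_along(idx), function(k) {
      .normalizeGenotype(records$gt[idx[k]], ref[k],
                         alts[[idx[k]]])
    }, "")[ok]
  }
  makeKeys(chrom[ok], pos[ok], ref[ok], alt[ok], gt = gt)
}

# "0/1" with ref C, alts c("T","G") -> "C/T" (alleles sorted).
.normalizeGenotype <- function(gt, ref, alts) {
  if (is.na(gt)) return("./.")
  alleles <- strsplit(gt, "[/|]")[[1]]
  bases <- vapply(alleles, function(a) {
    if (a == ".") return(".")
    ai <- suppressWarnings(as.integer(a))
    if (is.na(ai)) return(".")
    if (ai == 0) ref else if (ai <= length(alts)) alts[ai] else "."
  }, "")
  paste(sort(bases), collapse = "/")
}

#' Turn variant keys back into a minimal record table
#'
#' Convenience for writing category key lists as VCF and for building
#' fixtures: each key becomes one record.
#'
#' @param keys character vector of variant keys.
#' @param qual,depth optional per-key QUAL and DP values (recycled).
#' @param gt optional per-key genotype strings (recycled).
#' @return a record data.frame as produced by [readVariants()].
#' @export
keysToRecords <- function(keys, qual = NA_real_, depth = NA_integer_,
                          gt = NA_character_) {
  if (length(keys) == 0) return(.emptyRecords())
  f <- parseKeys(keys)
  data.frame(
    chrom = f$chrom, pos = f$pos, id = NA_character_,
    ref = f$ref, alt = f$alt,
    qual = rep_len(as.numeric(qual), nrow(f)),
    filter = "PASS",
    depth = rep_len(as.integer(depth), nrow(f)),
    gt = rep_len(as.character(gt), nrow(f)),
    effects = I(replicate(nrow(f), .emptyEffects(), simplify = FALSE)),
    stringsAsFactors = FALSE
  )
}

#' Write variant records as a plain-text VCF 4.2 file
#'
#' Emits a minimal, valid VCF that round-trips through [readVariants()]:
#' chrom/pos/ref/alt/qual (and DP, GT, ANN effects when present) are
#' preserved. Missing QUAL is written as ".".
#'
#' @param records record data.frame (or a character vector of keys,
#'   which is passed through [keysToRecords()]).
#' @param path output file path.
#' @param sample sample column name used when genotypes are present.
#' @return `path`, invisibly.
#' @export
writeVariantsVcf <- function(records, path, sample = "SAMPLE") {
  if (is.character(records)) records <- keysToRecords(records)
  stopifnot(is.data.frame(records))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write VCF to ", path))
  on.exit(close(con))
  hasGT <- nrow(records) > 0 && any(!is.na(records$gt))
  meta <- c(
    "##fileformat=VCFv4.2",
    "##source=vcbench",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations: 'Allele | Annotation | Putative_impact | Gene_Name | Gene_ID | Feature_type | Feature_ID'\">"
  )
  header <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (hasGT) {
    meta <- c(meta,
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
    header <- c(header, "FORMAT", sample)
  }
  writeLines(meta, con)
  writeLines(paste(header, collapse = "\t"), con)
  if (nrow(records) == 0) return(invisible(path))

  info <- vapply(seq_len(nrow(records)), function(j) {
    parts <- character()
    if (!is.na(records$depth[j]))
      parts <- c(parts, paste0("DP=", records$depth[j]))
    eff <- records$effects[[j]]
    if (is.data.frame(eff) && nrow(eff) > 0) {
      firstAlt <- strsplit(records$alt[j], ",", fixed = TRUE)[[1]][1]
      ann <- paste0("ANN=", paste(
        paste(firstAlt, eff$effect, ".", eff$gene, ".", ".", eff$transcript,
              sep = "|"), collapse = ","))
      parts <- c(parts, ann)
    }
    if (length(parts) == 0) "." else paste(parts, collapse = ";")
  }, "")

  fields <- cbind(
    records$chrom,
    format(records$pos, scientific = FALSE, trim = TRUE),
    ifelse(is.na(records$id), ".", records$id),
    records$ref,
    records$alt,
    ifelse(is.na(records$qual), ".",
           format(records$qual, scientific = FALSE, trim = TRUE, digits = 10)),
    ifelse(is.na(records$filter) | records$filter == "", ".", records$filter),
    info
  )
  if (hasGT) {
    samp <- paste(ifelse(is.na(records$gt), "./.", records$gt),
                  ifelse(is.na(records$depth), ".", records$depth), sep = ":")
    fields <- cbind(fields, "GT:DP", samp)
  }
  writeLines(apply(fields, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a BED file into a RegionSet
#'
#' Accepts BED3+ (0-based half-open); `track`/`browser`/comment lines are
#' skipped. Intervals are normalized (sorted, merged) on construction.
#'
#' @param path path to a BED file.
#' @return a [RegionSet-class] object.
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("no such BED file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(RegionSet())
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("BED parse error at line ", lineNo[which(nf < 3)[1]], " of ", path,
         ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0)
    stop("BED parse error at line ", lineNo[bad[1]], " of ", path,
         ": need integer 0 <= start < end, got '", lines[bad[1]], "'")
  RegionSet(chrom, start, end)
}

#' Write a RegionSet as BED3
#'
#' @param regions a [RegionSet-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(regions, path) {
  stopifnot(is(regions, "RegionSet"))
  df <- as.data.frame(regions)
  lines <- sprintf("%s\t%s\t%s", df$chrom,
                   format(df$start, scientific = FALSE, trim = TRUE),
                   format(df$end, scientific = FALSE, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}
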