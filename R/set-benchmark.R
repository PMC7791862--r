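# The core of the package: build the three sets A, B, C and derive the
# six discrete benchmark categories by set operations.

#' Build the benchmark sets A, B and C
#'
#' \describe{
#'   \item{A}{truth keys whose position lies in the target regions}
#'   \item{B}{query keys whose position lies in the target regions}
#'   \item{C}{query keys whose position lies in the high-confidence
#'     regions}
#' }
#' A is restricted to target regions only (not additionally to the
#' confident regions); this is what makes the incongruence category
#' I = A \\ (B union C) informative: truth variants on the panel that sit
#' outside the confident regions and were not called.
#'
#' Inputs are deduplicated: sets contain unique keys by definition.
#'
#' @param truth,query character vectors of variant keys ([toKeys()]).
#' @param target,confident [RegionSet-class] objects for the capture
#'   panel and the high-confidence regions.
#' @return a [BenchmarkSets-class] object.
#' @examples
#' t <- RegionSet("1", 0, 1000); h <- RegionSet("1", 0, 1000)
#' buildSets(makeKeys("1", 1:2, "A", "G"), makeKeys("1", c(1, 3), "A", "G"),
#'           t, h)
#' @export
buildSets <- function(truth, query, target, confident) {
  stopifnot(is(target, "RegionSet"), is(confident, "RegionSet"))
  if (totalLength(target) == 0)
    stop("empty target region set: the benchmark is undefined for a ",
         "targeted design without target regions")
  BenchmarkSets(A = sortKeys(unique(subsetKeys(truth, target))),
                B = sortKeys(unique(subsetKeys(query, target))),
                C = sortKeys(unique(subsetKeys(query, confident))))
}

#' Construct a BenchmarkSets object from key vectors
#'
#' Low-level constructor; [buildSets()] is the usual entry point.
#'
#' @param A,B,C character vectors of variant keys (deduplicated here).
#' @return a [BenchmarkSets-class] object.
#' @export
BenchmarkSets <- function(A = character(), B = character(), C = character()) {
  obj <- new("BenchmarkSets")
  obj@A <- unique(as.character(A))
  obj@B <- unique(as.character(B))
  obj@C <- unique(as.character(C))
  validObject(obj)
  obj
}

#' Derive the six discrete categories from the benchmark sets
#'
#' Pure set operations on A, B, C:
#' \describe{
#'   \item{TP}{`A` intersect `B` — calls matching the truth}
#'   \item{FP}{`(B intersect C) \\ A` — assessable calls absent from the
#'     truth}
#'   \item{FN}{`(A intersect C) \\ B` — truth variants in confident
#'     regions the caller missed}
#'   \item{NAC}{`B \\ (A union C)` — non-assessed calls: outside both the
#'     truth set and the confident regions}
#'   \item{O}{`C \\ (A union B)` — calls in confident regions out of the
#'     region of interest}
#'   \item{I}{`A \\ (B union C)` — incongruences: truth variants outside
#'     the confident regions, not called}
#' }
#' True negatives are deliberately not computed. The six sets are
#' pairwise disjoint, their union is A union B union C, and the counts
#' satisfy `|B| = tp + fp + nac` and `|A| = tp + fn + i`.
#'
#' @param sets a [BenchmarkSets-class] object.
#' @return a [DiscreteCounts-class] object; member lists are in
#'   canonical key order.
#' @examples
#' s <- BenchmarkSets(A = c("a", "b"), B = c("a", "c", "d"),
#'                    C = c("a", "c", "e"))
#' categoryCounts(computeDiscrete(s))
#' @export
computeDiscrete <- function(sets) {
  stopifnot(is(sets, "BenchmarkSets"))
  A <- sets@A; B <- sets@B; C <- sets@C
  members <- list(
    tp  = intersect(A, B),
    fp  = setdiff(intersect(B, C), A),
    fn  = setdiff(intersect(A, C), B),
    nac = setdiff(B, union(A, C)),
    o   = setdiff(C, union(A, B)),
    i   = setdiff(A, union(B, C))
  )
  members <- lapply(members, function(k) tryCatch(sortKeys(k),
                                                  error = function(e) sort(k)))
  new("DiscreteCounts",
      counts = vapply(members, length, 0L),
      members = members)
}

#' Multi-caller concordance: the full Venn partition
#'
#' Tallies, for n call sets, every cell of the Venn partition (the
#' 2^n - 1 membership signatures) plus the pairwise shared counts.
#'
#' @param callsets named list (>= 2 elements) of variant key vectors.
#' @return a list with elements
#'   \describe{
#'     \item{cells}{data.frame with columns `sets` (caller names joined
#'       by "&") and `count`, one row per signature including zeros;
#'       counts sum to the size of the union}
#'     \item{pairwise}{symmetric matrix of pairwise intersection sizes
#'       (diagonal: set sizes)}
#'   }
#' @examples
#' concordance(list(x = c("a", "b"), y = c("b", "c")))
#' @export
concordance <- function(callsets) {
  stopifnot(is.list(callsets), length(callsets) >= 2)
  nm <- names(callsets)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    stop("callsets must have unique non-empty names")
  callsets <- lapply(callsets, unique)
  universe <- unique(unlist(callsets, use.names = FALSE))
  n <- length(callsets)

  membership <- vapply(callsets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  if (length(universe) == 0) membership <- matrix(FALSE, 0, n)

  combos <- expand.grid(rep(list(c(FALSE, TRUE)), n))[-1, , drop = FALSE]
  names(combos) <- nm
  sig <- apply(membership, 1, function(row) paste(nm[row], collapse = "&"))
  lab <- apply(combos, 1, function(row) paste(nm[as.logical(row)], collapse = "&"))
  counts <- as.integer(table(factor(sig, levels = lab)))

  pairwise <- matrix(0L, n, n, dimnames = list(nm, nm))
  for (a in seq_len(n)) for (b in seq_len(n))
    pairwise[a, b] <- length(intersect(callsets[[a]], callsets[[b]]))

  list(cells = data.frame(sets = lab, count = counts,
                          stringsAsFactors = FALSE, row.names = NULL),
       pairwise = pairwise)
}
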