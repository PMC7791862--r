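---
title: "Benchmarking variant callers with a set-theory model"
author: "vcbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking variant callers with a set-theory model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcbench)
```

## The problem

Validating a variant-calling pipeline for a targeted sequencing assay
means comparing its calls against a gold-standard call set (for example
the GIAB/NIST NA12878 reference calls) — but only where such a comparison
is meaningful: inside the capture panel, and inside the regions where the
truth set is considered complete ("high-confidence" regions). Outside
those regions a call is neither right nor wrong; it is unassessable.
Generic accuracy tooling tends to hide this stratification. `vcbench`
makes it the core of the model, so that every reported number is a set
cardinality or a ratio of set cardinalities, and every set is a concrete,
writable list of variants.

## The model and its assumptions

Variants are reduced to keys `chrom:pos:ref:alt`. Three sets are formed:

* **A** — truth keys with position inside the target regions,
* **B** — query keys inside the target regions,
* **C** — query keys inside the high-confidence regions,

and six pairwise-disjoint categories are derived purely by set algebra:
TP = A∩B, FP = (B∩C)\\A, FN = (A∩C)\\B, NAC = B\\(A∪C), O = C\\(A∪B),
I = A\\(B∪C). Their union is A∪B∪C, and the partition identities
|B| = TP+FP+NAC and |A| = TP+FN+I hold for every input; the test suite
asserts them on every fixture. True negatives are not computed: without
an enumerable universe of non-variant positions they have no stable
interpretation for a targeted panel.

Assumptions worth stating explicitly:

* **Allele-level matching.** Two calls match when chromosome, position,
  reference and alternate allele agree. A genotype-aware mode
  (`genotype = TRUE` in `toKeys()`; `genotypeMatch = TRUE` in
  `runBenchmark()`) additionally requires identical unordered genotype
  allele sets. Allele-level is the default because the discrete
  categories and all downstream ratios are already fully determined by
  it for SNP benchmarking.
* **SNP scope.** `snpOnly = TRUE` keeps 1 bp→1 bp substitutions.
  Multiallelic records are split into one key per alternate allele; no
  left-alignment or indel normalisation is performed, because SNP keys
  are already canonical. Indels pass through when `snpOnly = FALSE`, but
  cross-representation indel matching (vcfeval-style haplotype
  comparison) is out of scope and flagged as a limitation.
* **Region membership by POS.** A variant is inside a region iff its
  1-based POS base is covered (BED is 0-based half-open; the conversion
  `pos − 1` is fixed package-wide). For SNPs this is exact; for indels it
  is the common single-anchor convention.
* **A is restricted to target regions only**, not additionally to the
  confident regions. That is what makes I = A\\(B∪C) informative: truth
  variants on the panel that sit outside the confident regions and were
  not called.

### A structural consequence: FN is always empty

Because B and C are derived from the *same* query call set, any key in
A∩C is a query call whose position is in the target (it is in A, and A
only contains target-region keys), hence it is in B — so FN = (A∩C)\\B is
empty for every possible input. The model's FN row is therefore a
consistency indicator rather than a measurable error mode; a truth
variant the caller genuinely missed appears in I instead. The fixture
generator enforces this honestly: requesting `fn > 0` is rejected as
unsatisfiable with an explanation, rather than silently planting
variants that would surface elsewhere.

## Filtering and tunable parameters

| parameter | default | meaning |
|-----------|---------|---------|
| `minQual` | 20 | query calls must have QUAL **strictly greater** (unitless Phred-scaled call quality) |
| `minDepth` | 10 | query calls must have DP **strictly greater** (reads) |
| `snpOnly` | TRUE | restrict keys to single-base substitutions |
| `genotypeMatch` | FALSE | require identical unordered genotypes |

The strict inequalities QUAL > 20, DP > 10 are the conventional hard
filter applied to caller output for targeted panels. Records lacking
QUAL or DP fail the filter: a call that cannot demonstrate its quality
is treated conservatively, mirroring how VCF filtering tools treat
missing annotation in practice. DP is taken from the named sample's
FORMAT field when present, falling back to INFO. The truth VCF is used
unfiltered — the gold standard is not subject to the pipeline's
post-calling filter.

Reported rounding follows benchmark-table convention: three decimals for
recall/precision/Frac_NA/F1, five for the Ts/Tv ratio, four for the
missense/silent ratio. Internal computation is unrounded, and F1 is
computed from unrounded precision and recall; note that rounding P and R
*before* the harmonic mean can differ from the correct value in the
third decimal, which is why the package never does it. Undefined metrics
(zero denominators) are reported as `NA`, never coerced to 0 or 1.

## Summary statistics

* **Ts/Tv**: transitions are A↔G and C↔T; everything else among
  single-base substitutions is a transversion. Exome-like panels
  typically sit near 3; higher usually indicates a cleaner call set.
* **Missense/silent** is counted at the *transcript* level from
  SnpEff-style `ANN=` annotations (one variant hitting several
  transcripts contributes several entries), so counts may exceed the
  number of variants. Labels other than missense/synonymous are tallied
  separately and ignored by the ratio.
* **Variant rate** is reported as "1 per `round(span/n)` bases". The
  reference span is configurable and defaults to the GRCh37 primary
  assembly total (3,095,677,412 bp), because a genome-wide rate is the
  convention in caller summary tables even for targeted data; pass the
  covered target length for an on-panel rate.

## ROC analysis

Each assessed call in B becomes a scored call: label = present in A,
score = QUAL. This construction is deliberately explicit (and recorded
in the report metadata) because discrimination analyses are meaningless
unless the positive/negative definition is stated. The curve sweeps
thresholds over distinct scores descending, grouping ties; the AUC is
the Mann–Whitney rank estimate (ties half credit), which equals the
trapezoidal area under the emitted points to machine precision — the
suite checks both against an O(n²) pair-counting oracle.

Significance uses the Hanley–McNeil closed-form standard error
(Q1 = A/(2−A), Q2 = 2A²/(1+A)). For the test against chance the SE is
evaluated at the null (A = 0.5), where the closed form reduces exactly
to the null Mann–Whitney variance (n₊+n₋+1)/(12·n₊·n₋); this choice
gives calibrated p-values, which the suite verifies by a
Kolmogorov–Smirnov uniformity check over 2,000 null replicates (50
positives and 50 negatives each — large enough for the normal
approximation, small enough to keep the check inside a few seconds).
Unpaired curve comparison uses z = (A₁−A₂)/√(SE₁²+SE₂²); paired
comparison uses the DeLong covariance of placement values on the keys
shared by both call sets. p-values below 5×10⁻⁴ are *printed* as
"0.000" in the human-readable tables, with exact values retained in the
JSON output.

## What the synthetic fixtures emulate — and what they do not

`generateFixture()` lays each synthetic chromosome out in four zones
(target∩confident, target-only, confident-only, neither) and places each
requested variant so that its membership signature lands it in exactly
the requested category; positions are drawn without replacement so keys
never collide, and a single RNG stream seeded once (zones → positions →
alleles → QUAL/DP → decoys) makes bundles byte-reproducible from the
seed. Default generator conditions mirror a targeted benchmark at panel
scale: 1 Mb chromosomes, half the chromosome on-target, half of that
high-confidence, planted QUAL centred at 60 ± 10 (clipped to pass the
default filter), DP uniform on 20–100, and a 0.7 transition bias.
Decoy calls (sub-threshold QUAL or DP) verify the filter stage: they
must vanish before set construction.

This emulates region geometry, category structure, filter behaviour and
quality-score separation. It does **not** emulate read-level error
processes, alignment artefacts, indel representation ambiguity, linkage
or allele-frequency structure. Passing the recovery tests therefore
demonstrates that the set algebra, interval arithmetic, filtering and
reporting are correct — it does not certify any particular caller's
accuracy on real sequencing data, which additionally depends on
everything upstream of the VCF.

## Numerical and design choices

* **Chromosome normalisation** strips a leading "chr" case-insensitively
  and upper-cases the rest, so GRCh37 ("1") and UCSC ("chr1") dialects
  compare equal. Output ordering is natural: 1…22, X, Y, MT, then other
  contigs alphabetically.
* **Interval normalisation** merges overlapping *and adjacent* intervals
  so a covered-base set has exactly one representation; intersection and
  length arithmetic are delegated to GenomicRanges and cross-checked
  against a per-base bitmap oracle in the suite.
* **Duplicate keys** within one call set are deduplicated at set
  construction (sets contain unique elements); for ROC scoring the
  maximal QUAL per key is kept.
* **Degenerate inputs**: an empty target region set is an error (a
  targeted benchmark is undefined without a panel); an empty
  high-confidence set degrades with a warning (C = ∅, so FP/FN/O are
  zero by construction and only NAC and I remain informative); undefined
  ratios are `NA`.
* **Deterministic output ordering** of all key lists (chromosome, then
  position, reference, alternate) keeps reports diffable across runs.

## Known limitations

Indel comparison across representations, gVCF and structural-variant
records, confidence intervals on precision/recall, and stratification of
metrics by variant type or genomic context are out of scope. The Ts/Tv
and functional-class statistics assume SNP keys and transcript-level
annotations respectively; both degrade gracefully (unclassifiable keys
are ignored, missing annotations count as zero) but are only as good as
the annotations supplied.

Problem sizes used by the test suite and the acceptance script — 10 kb
oracle chromosomes, ≤1,000-element brute-force instances, 100 random
fixture specifications, 2,000 null ROC replicates — were chosen as the
smallest sizes at which the brute-force oracles still exercise every
code path; all of them rerun in well under a minute on one core.
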