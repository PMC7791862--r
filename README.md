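# vcbench — set-theory benchmarking of variant calling pipelines

`vcbench` benchmarks the output of variant callers against a gold-standard
call set using an explicit, auditable set-theory model. It is aimed at
people validating targeted-sequencing pipelines (gene panels, clinical
assays) who need to know not just *how accurate* a caller is, but *which
variants* fall into each evaluation category — and who want every number
in the report to be re-derivable from a plain set operation.

## The model

Three sets of variant keys (`chrom:pos:ref:alt`, SNPs by default) are
built from four inputs — a truth VCF, a query VCF, a target-capture BED
and a high-confidence-region BED:

| set | definition |
|-----|------------|
| A | truth variants in the **target** regions |
| B | query variants in the **target** regions |
| C | query variants in the **high-confidence** regions |

Six pairwise-disjoint categories follow by set algebra:

    TP  = A ∩ B            calls that match the truth
    FP  = (B ∩ C) \ A      assessable calls absent from the truth
    FN  = (A ∩ C) \ B      truth variants in confident regions, missed
    NAC = B \ (A ∪ C)      non-assessed calls (outside truth and confident regions)
    O   = C \ (A ∪ B)      calls in confident regions, out of the region of interest
    I   = A \ (B ∪ C)      incongruences: truth variants outside confident regions, not called

True negatives are deliberately not computed. The partition identities
`|B| = TP + FP + NAC` and `|A| = TP + FN + I` hold on every input and are
asserted throughout the test suite. (A consequence of the definitions
worth knowing: because B and C derive from the same query call set, FN is
empty for every possible input — a missed truth variant surfaces in I.)

Continuous metrics are ratios of these counts:

    Recall    = TP / (TP + FN)
    Precision = TP / (TP + FP)
    Frac_NA   = NAC / |B|
    F1        = 2·P·R / (P + R)     (from unrounded P and R)

On top of the core model the package provides call-set summary statistics
(Ts/Tv ratio, transcript-level missense/silent ratio, per-chromosome
counts, variant rate), n-caller Venn concordance, and ROC/AUC comparison
of callers (rank AUC, Hanley–McNeil standard error, z-tests, DeLong
paired comparison). Query calls are filtered with the usual hard filter
for targeted panels before set construction: QUAL > 20 and DP > 10,
strict inequalities, missing values fail.

A seeded synthetic-fixture generator (`generateFixture()`,
`generateTrio()`) emits complete benchmark bundles — truth VCF, query
VCF, target BED, confident BED, manifest — with *exactly* controlled
category counts, so the whole pipeline is testable without any external
download.

## Worked example

```r
library(vcbench)

# a synthetic bundle with known category counts (plus 10 sub-threshold
# decoy calls that the QUAL/DP filter must remove)
generateFixture(fixtureSpec(tp = 233, fp = 3, nac = 23, i = 2,
                            decoys = 10, seed = 42), dir = "fixture")

res <- runBenchmark("fixture/truth.vcf",
                    c(freebayes = "fixture/query.vcf"),
                    "fixture/target.bed", "fixture/confident.bed",
                    outdir = "report")
#> INFO: target 500,000 bp, confident 500,000 bp, intersection 250,000 bp (50.0% of target)
#> INFO: freebayes: |A| = 235, |B| = 259, |C| = 236

res$metrics
#>      Caller  TP FP FN I NAC Recall Precision Frac_NA F1_Score
#> 1 freebayes 233  3  0 2  23      1     0.987   0.089    0.994
```

The planted counts come back exactly: 259 filtered query calls in the
target regions split into 233 TP + 3 FP + 23 NAC; the truth set of 235
splits into 233 TP + 2 I. Precision is 233/236 = 0.987, Frac_NA is
23/259 = 0.089, and recall is 1 because FN = 0. Each category is also a
concrete list of variants, written as `report/freebayes/tp.vcf`,
`fp.vcf`, `fn.vcf`, `nac.vcf`, `o.vcf`, `i.vcf`:

```r
head(categoryKeys(res$discrete$freebayes, "nac"), 3)
#> [1] "1:258324:T:C" "1:263972:C:T" "1:265018:C:T"

tv <- tsTv(setB(res$sets$freebayes))
sprintf("Ts/Tv: %d/%d = %.5f", tv$ts, tv$tv, tv$ratio)
#> [1] "Ts/Tv: 185/74 = 2.50000"
```

`runRocReport()` adds per-caller ROC curves (label: call present in A;
score: QUAL) and pairwise AUC comparisons; `concordance()` tallies every
cell of the n-caller Venn partition. A thin command-line wrapper with
subcommands `bench`, `roc`, `simulate` and `concordance` lives at
`inst/scripts/vcbench.R`.

## The methods vignette

`vignettes/set-theory-benchmarking.Rmd` documents the model and its
assumptions, the filtering and matching conventions, what the synthetic
fixtures do and do not emulate, the ROC construction and its
calibration, and the package's numerical and design choices.
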