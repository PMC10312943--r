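# pamlcat

Molecular categorization and risk stratification of pediatric acute myeloid
leukemia (pAML).

Pediatric AML is driven largely by structural alterations — `KMT2A`, `NUP98`
or `GLIS` rearrangements, `UBTF` tandem duplications, enhancer-hijacking
activation of `MECOM`/`BCL11B`/`MNX1` — many of which are missing from
classification schemes built on adult AML. `pamlcat` implements an
RNA-seq-oriented diagnostic framework for this disease: each sample is
assigned to exactly one of 23 mutually exclusive molecular categories (or
Unclassified) by a precedence-ordered rule engine over its lesion calls,
allele-specific-expression evidence, and expression signatures, and the
categories feed a prognostic framework of three risk groups crossed with
minimal-residual-disease (MRD) status.

The package is aimed at computational hematology/oncology groups who have
lesion-call tables (fusions/SVs, SNV/indels with VAF and read support,
ITD/PTD calls, CNV segments), per-gene SNP-marker read counts, an expression
count matrix, and clinical follow-up — and want a tested, deterministic
implementation of the categorization and outcome framework. Because the
motivating patient data are controlled-access, the package ships a seeded
synthetic-cohort generator calibrated to the published cohort frequencies,
so the entire pipeline is exercised end-to-end without any patient data.

## The model in brief

* **Categories.** A declarative, versioned ruleset
  (`inst/extdata/categories_v1.yaml`) defines the 23 categories in three
  precedence tiers: tier 1, fusion/SV-defined (e.g. `KMT2Ar`, `NUP98r`,
  `RUNX1::RUNX1T1`, `CBFB::MYH11`, `DEK::NUP214`, APL, `GLISr`,
  `FET::ETS`, `PICALM::MLLT10`, `KAT6Ar`, and `MECOM`/`BCL11B`/`MNX1` by SV
  *or* allele-specific + outlier expression); tier 2, mutation/tandem-
  duplication-defined (`NPM1`, `CEBPA`, `UBTF`, `CBFB`-GDXY); tier 3,
  expression-gated entities (`GATA1`, `HOXr`, `KMT2A`-PTD) that apply only
  without a prior driver and with a consistent signature. The first firing
  rule by tier wins; two distinct categories firing in one tier is surfaced
  as a ruleset error, never silently resolved.
* **ASE test.** For `MECOM`/`BCL11B`/`MNX1`, allele-specific expression at
  DNA-heterozygous SNP markers (coverage ≥ 10, DNA VAF in [0.2, 0.8]) is
  tested per marker with an exact two-sided binomial test at p = 0.5 and
  summarized by the median p-value.
* **Filters.** RNA-based mutation calls are post-filtered exactly at the
  published thresholds (alt reads ≤ 5 or VAF ≤ 5% removed; identical
  variants in > 5% of cases flagged as germline/artifact, with a hotspot
  whitelist).
* **Signatures.** Expressed genes (CPM ≥ 10 in ≥ 5 samples) are summarized
  as floored log2 CPM; HOXA/HOXB cluster mean scores with 2-means-derived
  thresholds call the HOXA-like vs HOXB-like superfamily signature.
* **Statistics.** Pairwise lesion co-occurrence / mutual exclusivity by
  exact two-sided Fisher tests with Benjamini–Hochberg adjustment.
* **Risk.** Kaplan–Meier / log-rank summaries, a censored-data
  recursive-partitioning grouping of categories (greedy log-rank splits
  over landmark-ordered categories with local refinement), the packaged
  category → {Low, Intermediate, High} mapping, and six strata =
  risk group × MRD.

## Worked example

```r
library(pamlcat)

cohort <- generate_cohort(seed = 42)        # default config: n = 895
#> paml_cohort: 895 samples | 631 fusions, 1442 mutations, 143 CNV segments, 405 ASE markers
#>   expression: 105 genes x 895 samples

calls <- classify_cohort(cohort)
cov <- cohort_coverage(calls)
sprintf("defined-category coverage: %.1f%%", 100 * cov$coverage)
#> "defined-category coverage: 91.3%"

head(sort(cov$counts, decreasing = TRUE), 6)
#>         KMT2Ar RUNX1::RUNX1T1    CBFB::MYH11         NUP98r   Unclassified
#>            193            110             89             78             78
#>           NPM1
#>             76

strat <- stratify_cohort(calls, cohort$clinical, endpoint = "OS")
km5 <- vapply(split(strat, strat$stratum),
              function(g) km_at(km_estimate(g$time, g$event), 5), 0)
round(km5, 2)
#>          Low/MRD-          Low/MRD+ Intermediate/MRD- Intermediate/MRD+
#>              0.87              0.80              0.68              0.41
#>         High/MRD-         High/MRD+
#>              0.56              0.28
```

The coverage (91.3% of 895 samples in a defined category, `KMT2Ar` the
largest at ~20%) reproduces the published cohort structure, and five-year
overall survival decreases across the six strata from `Low/MRD-` (0.87) to
`High/MRD+` (0.28); the one inversion above (`Intermediate/MRD+` vs
`High/MRD-`) reflects the small size of the High/MRD- stratum in a single
simulated cohort.

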