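# mytBTN

Detection and quantification of bivalve transmissible neoplasia (BTN) in
*Mytilus* mussels from multi-locus genetic data.

Disseminated neoplasia, a leukemia-like cancer of bivalves, is in some
species a *transmissible* cancer: a clonal cell lineage that passes
between animals as an infectious allograft, carrying the genome of its
long-dead founder. `mytBTN` implements the inference chain that
distinguishes such a lineage from conventional cancer:

* **Clone curation** — cloned Sanger sequences per individual × locus are
  deduplicated; single-clone sequences within <0.5% of a multi-clone
  allele (2 differences for *EF1α*/*H4*, 3 for the mitochondrial control
  region) are absorbed as PCR errors; singletons explainable as a
  single-crossover PCR recombination of two alleles from the same sample
  are discarded.
* **Lineage detection** — an individual with more alleles than its ploidy
  (or the doubly-uniparental mitochondrial expectation) allows is
  *supernumerary*; alleles shared across ≥2 such diseased individuals and
  absent from every normal (within a 1-difference near-match radius that
  tolerates de novo mutations like a one-SNP second copy of an allele)
  form the cancer lineage's per-locus profile; profiles from different
  cohorts are compared for lineage identity.
* **Phylogenetics** — neighbor-joining trees on p/Jukes-Cantor distances
  (gaps treated as missing, pairwise deletion), bootstrap supports with
  sub-50 values suppressed, midpoint rooting, and assignment of the
  cancer's species of origin as the species whose normal alleles enclose
  the cancer alleles in the minimal clade.
* **Mitochondrial recombination** — a maximum chi-square scan over
  informative sites locates female/male recombination breakpoints
  (interval reported between informative sites, 0-based half-open),
  heteroplasmy/loss/replacement bookkeeping, and head-to-tail
  tandem-repeat detection with copy number estimated from qPCR excess.
* **Allele-specific qPCR** — standard curves (Cq on log10 copies,
  efficiency `10^(-1/slope) - 1`), triplicate means, and the fraction
  `specific/universal` with a 10 copies/reaction limit of detection and a
  5000 copies/reaction universal floor (upper limit of detection
  10/5000 = 0.2%); fractions above 100% flag a tandem repeat.
* **Diagnostic-SNP (KASP) panel** — per-locus fluorescence transform
  `y' = y/(x+y)`, the compound multi-locus mean over 13 diagnostic loci,
  and classification tolerating introgression (signal at ≤1 locus is
  normal, at 2 introgressed-normal, at ≥3 BTN-positive).
* **Synthetic cohorts** — a generator for species allele pools, DUI
  mitochondria, polyploid cancer genotypes, clone noise, qPCR plates and
  KASP fluorescence, with planted truth exported for every
  parameter-recovery test, plus `reference_cohort()`, a deterministic
  synthetic counterpart of a published-style multi-species study design.

## Worked example

```r
library(mytBTN)

ref    <- reference_cohort(seed = 1)          # synthetic study design
clones <- reference_clone_sets(ref, seed = 2) # 12 clones / individual / locus
run <- run_pipeline(
  clones, ref$sheet, btn_config(loci = ref$loci, seed = 2),
  qpcr_plate   = reference_qpcr_plate(ref, seed = 3),
  kasp_records = reference_kasp(ref, seed = 4),
  mito_parents = list(mtCR = parental_pair(
    ref$lineages$btn2_sa$mito_parents$mtCR$female,
    ref$lineages$btn2_sa$mito_parents$mtCR$male)))
run
#> Bivalve transmissible neoplasia detection run
#>   32 genotyped individuals
#>   lineage profile: 19 cancer-associated alleles over 4 loci
#>   classifications: lineage-positive=15, non-lineage neoplasia=2, normal=15
```

The widely shared profile alleles are the planted cancer genotype — two
nuclear alleles per locus (the *EF1α* pair carried by 13 diseased animals,
with the European one-SNP second copy right behind), one major
control-region recombinant and one COI allele:

```r
run$profile[run$profile$n_diseased > 2, c("locus", "label", "n_diseased")]
#>   locus label n_diseased
#> 1  EF1a     A         13
#> 2  EF1a     B         13
#> 3  EF1a     C         12
#> 4    H4     A         13
#> 5    H4     B         13
#> 6    H4     C          3
#> 7  mtCR     A         13
#> 8 mtCOI     A         11
```

Per-individual classification separates the lineage carriers from the two
diseased Chilean animals that carry none of the lineage's markers:

```r
subset(run$classification, diagnosis == "cancer",
       c(id, lineage_loci, classification))
#>        id lineage_loci        classification
#>     Mch23            4      lineage-positive
#>     Mch41            4      lineage-positive
#>  Castro49            0 non-lineage neoplasia
#>  Castro84            0 non-lineage neoplasia
#>       Ch5            4      lineage-positive
#>   ...                (15 lineage-positive in all)
```

The detected control-region allele is a female/male recombinant, and the
qPCR fraction matrix shows the study's quantitative signatures — the major
recombinant (`mtCR:D`) above 100% because it sits in a tandem repeat, the
minor heteroplasmic allele (`mtCR:C`) at a fraction of a percent in
*M. chilensis* carriers and undetectable (`U`) in the loss subgroup, and
all loci `U` in non-carriers:

```r
run$breakpoints[["mtCR:A"]]
#> <breakpoint call: single-crossover; 137 informative sites; chi-square 137.00>
#>   female -> male, crossover interval [541, 543) (0-based)

fraction_matrix(run$fractions)[c("Mch41", "Ch5", "Castro49", "Mch3"), ]
#>          mtCOI:B mtCR:C mtCR:D   EF1a:H  H4:KNS  H4:RM
#> Mch41    "50.3%" "0.3%" "164.1%" "23.9%" "29.9%" "30.5%"
#> Ch5      "58.0%" "U"    "189.7%" "27.4%" "27.8%" "28.4%"
#> Castro49 "U"     "U"    "U"      "U"     "U"     "U"
#> Mch3     "U"     "U"    "U"      "U"     "U"     "U"
```

See the methods vignette (`vignettes/btn-detection-methods.Rmd`) for the
model, rules, parameter defaults and limitations.

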