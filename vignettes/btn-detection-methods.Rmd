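---
title: "Detecting bivalve transmissible neoplasia from multi-locus genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting bivalve transmissible neoplasia from multi-locus genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mytBTN)
```

## The inference problem

Disseminated neoplasia is a leukemia-like cancer of bivalves. In several
species it is not a conventional cancer but a *bivalve transmissible
neoplasia* (BTN): a clonal cell lineage that moves between host animals as
an infectious allograft. A BTN carries the genome of its long-dead founder
animal, so its genetic signature inside a host is distinctive:

* **Supernumerary alleles.** A diploid individual carries at most two
  alleles at a nuclear locus. DNA from a diseased animal that mixes host
  and cancer genotypes yields three to five distinct alleles.
* **Shared cancer-associated alleles.** The same extra alleles recur in
  *unrelated* diseased individuals — even in different populations or host
  species — and are absent from normal animals.
* **A foreign species of origin.** On a phylogeny, the cancer-associated
  alleles cluster inside the source species' diversity, not the host's.
* **Quantitative signals.** Allele-specific qPCR measures the fraction of
  templates carrying a cancer allele, and species-diagnostic SNP assays
  light up across the whole panel when cancer DNA from another species is
  present.

`mytBTN` implements this entire inference chain for the *Mytilus* system
(hosts *M. chilensis* and *M. edulis*; cancer lineage of *M. trossulus*
origin), from raw cloned Sanger sequences to a per-individual verdict:
`normal`, `lineage-positive`, or `non-lineage neoplasia` (a diseased animal
without the lineage's markers, i.e. conventional cancer or a different
lineage). Every stage is testable without external data through a
synthetic-cohort generator that exports its planted truth.

## Clone curation

Cloning a PCR product samples single molecules, so the 6–12 clones
sequenced per individual and locus contain PCR point errors and PCR-
recombination chimeras alongside the true alleles. Curation applies three
rules per individual × locus, in order:

1. **Deduplication** of identical clone sequences (descending-count order,
   lexicographic tie-break, so results are independent of clone order).
2. **Singleton collapse.** A sequence seen in a single clone that differs
   by at most the per-locus threshold — two differences for the nuclear
   loci, three for the longer mitochondrial control region, under 0.5% of
   the aligned length — from an allele supported by more than one clone is
   treated as an error of that allele; its clone is added to the closer
   (then higher-support, then lexicographically smaller) allele's support
   and the absorbed sequence is recorded.
3. **Chimera discard.** A remaining singleton is discarded iff some
   ordered pair of multi-clone alleles (A, B) explains it with a single
   crossover: it matches A at every informative site left of one point and
   B at every informative site right of it, with at least two informative
   sites supporting each segment. The two-site minimum keeps a lone point
   difference (indistinguishable from a PCR error, and handled by rule 2)
   from being read as a crossover, and restricting parents to multi-clone
   calls keeps near-duplicate singleton pairs from spuriously "explaining"
   every other call.

Distances are Hamming counts over aligned positions; a gap versus a base is
one difference and `N` matches anything. Retained non-chimeric singletons
are kept but flagged `singleton` (low confidence): they count as presence
evidence downstream but are never presented as confirmed alleles.

Measured on planted clone sets (four templates: heterozygous host plus a
tetraploid cancer genotype at equal template fractions, 12 clones,
0.001 errors/site, 10% chimeras), curation achieves precision ≈ 1.0 over
presented (multi-clone) alleles and recall ≈ 0.97 of the templates actually
sampled, scoring matches at a one-difference tolerance — the same radius
the lineage stage uses, since a residual single PCR error on a rescued
singleton is not a curation failure the downstream logic would notice.

## Lineage detection

An allele is **cancer-associated** when it is present (within a
near-match radius of 1 difference, which accommodates de novo mutations of
the clonal lineage such as a second copy of an allele acquiring one
substitution after genome duplication) in at least two diseased
individuals and absent, within the same radius, from every normal
individual.

Two guards keep identity-by-state host alleles out of the profile, both
needed because realistic normal panels are small (three to seven animals
per species in the study design this package emulates):

* Candidate alleles must have multi-clone support in at least one diseased
  individual, or be called *identically* in two — two independent
  identical calls of a ~500-site sequence cannot be the same random PCR
  error.
* Sharing is counted only over diseased individuals whose genotype at the
  locus is **anomalous**: more distinct calls than a normal animal can
  carry. The expectation is 2 for a diploid nuclear locus; for
  mitochondrial loci it is set by doubly-uniparental inheritance (DUI) —
  2 where the assay amplifies the male lineage alongside the female
  (control region), 1 where it does not (COI). An allele shared only among
  normal-looking diseased genotypes is indistinguishable from host-allele
  identity by state and is left out.

Near-duplicate profile alleles within the radius are grouped into
polyploid families (both sequences retained). Profiles from two cohorts
are compared locus by locus (`identical`, `near-identical` with the
differences listed, or `distinct`); the overall same-lineage call requires
all shared nuclear loci identical or near-identical, while mitochondrial
discordance is reported but does not veto, because a transmissible lineage
can lose heteroplasmy or capture a host mitochondrial genome.

Individuals are classified with multi-locus concordance: a diseased animal
is `lineage-positive` when it carries profile alleles at two or more loci
(configurable; a qPCR or SNP-panel positive can also upgrade it), and
`non-lineage neoplasia` otherwise. On simulated cohorts of 60 animals at
10% prevalence the detected allele set equals the planted founder set in
≈98% of replicates; the residual failures are cohorts that drew fewer than
two diseased animals, where sharing is undefined.

## Trees and the species of origin

The claims the tree stage supports are clade-membership claims — which
species' diversity the cancer alleles nest within, and whether two cancer
lineages could be one — and these are robust to substitution-model choice
at within-genus divergences. Trees are therefore built by neighbor
joining on Jukes-Cantor distances (p-distance `p` mapped through
`-3/4 log(1 - 4p/3)`), with gaps and `N` treated as missing data and
excluded pairwise. Nonparametric bootstrap (column resampling, NJ per
replicate, bipartition frequencies) supplies supports; rendered output
suppresses supports below 50. Trees are midpoint-rooted. The species of
origin is the species of the normal alleles inside the minimal clade
containing a lineage's cancer alleles, computed after dropping
other-lineage cancer leaves and known introgressed/hybrid alleles (which
are reported separately rather than weighted into the verdict); two
lineages are independent when their alleles do not form an exclusive clade
together. Alignments can be exported as FASTA for external
maximum-likelihood tools when model-based branch lengths are wanted.

## Mitochondrial recombinants, heteroplasmy, and the tandem repeat

Cancer-associated control-region alleles are female/male recombinants.
`find_breakpoint()` types each informative site (where the female and male
references differ) as matching one parent, scans all split points of that
match vector with a 2×2 chi-square statistic, and calls a single crossover
when the best split is significant (χ² ≥ 3.84, the 5% point at 1 df) and
each side matches one parent at ≥90% of its informative sites. Queries
within one discordant site of a single parent are `non-recombinant` (noise
floor); significant but impure splits are `complex`; fewer than four
usable informative sites is `uninformative`. The crossover interval is
reported 0-based half-open between the flanking informative sites, because
a crossover cannot be located inside a tract where the parents agree; on
planted recombinants with 40 informative sites the true splice point falls
inside the reported interval in >95% of replicates. The verdict is
invariant to swapping the parental labels.

Heteroplasmy bookkeeping combines clone support with qPCR detectability:
a minor heteroplasmic allele can sit far below the cloning sampling depth
(at 0.5% of cancer mitochondrial templates it is essentially never cloned
at 12 clones) yet be detected comfortably by allele-specific qPCR, so
either evidence stream establishes presence. Loss is flagged when a
profile allele is undetectable in a lineage carrier; replacement when a
shared cancer mitochondrial allele is closer to host-species than to
source-species references. Control-region tandem repeats are confirmed by
a head-to-tail junction search (the in-silico analogue of amplifying
across the repeat junction with outward-facing primers) and sized from the
qPCR excess: an allele present in k tandem copies per genome yields an
allele-specific/universal fraction of k times the template fraction —
the mechanism behind fractions above 100%.

## qPCR quantification

Standard curves are least-squares fits of Cq on log10 copies over a
serial dilution (10^1–10^7 copies in triplicate); amplification efficiency
`10^(-1/slope) - 1` is flagged outside [0.6, 1.2]. Copies are inverted per
replicate and averaged (plain triplicate means, no outlier handling). The
cancer-allele fraction is the mean allele-specific copies over the mean
universal copies, with a total status logic: a sample is discarded when
any universal reaction yields under 5000 copies/reaction; an
allele-specific mean below 10 copies/reaction is `undetectable` (every
such record reports the upper limit of detection 10/5000 = 0.2%);
fractions above 1 are `over_unity` (the tandem-repeat signature);
otherwise `detected`. The fraction is scale-invariant and, in simulation,
tracks the planted burden with Spearman correlation > 0.99 at 10%
lognormal copy noise.

## The diagnostic-SNP panel

KASP genotyping returns two endpoint fluorescence values per locus: x for
the host allele and y for the *M. trossulus*-specific allele. The
transform `y' = y/(x + y)` is scale-invariant and maps host homozygotes
near 0, heterozygotes near 0.5 and trossulus homozygotes near 1; the
compound multi-locus estimate is the mean of y' over the 13 diagnostic
loci (missing records excluded and counted). Because incomplete lineage
sorting and introgression let a non-hybrid animal be heterozygous at one —
very rarely two — diagnostic loci, but never more, classification counts
loci with y' at or above 0.2 (the gap between the zero cluster and the
heterozygote cluster): at most one is `normal`, below three is
`introgressed-normal`, three or more is `BTN-positive`. Both the count and
the compound estimate are reported, since either can serve as the
operative classifier; at the defaults every simulated cancer sample is a
clear outlier in both.

## The synthetic generator and what passing tests mean

Alleles are generated on a star genealogy: one ancestor per locus, species
ancestors mutated from it at rates fit to a requested divergence matrix
(with the expected private-mutation load debited so realized inter-pool
divergence matches the request within the 30% calibration contract), and
alleles as species ancestors plus Poisson-distributed private
substitutions, kept at least three differences apart so they are
distinguishable above the curation thresholds. Mitochondrial loci carry a
deeply diverged (15%) male haplotype pool, modelling DUI. Cohorts draw
diploid nuclear genotypes by pool frequency, a female mitochondrial allele
always and a male one with probability 0.5 (matching roughly half of
individuals yielding male alleles), optional allospecific alleles for
hybrids, and optional introgression at diagnostic SNP loci (mostly one
locus, a tenth of the time two). A cancer lineage is a tetraploid founder
genotype — two founder alleles per nuclear locus at two copies each, with
an optional one-substitution near-duplicate second copy — plus
control-region female/male recombinants at two distinct crossover points
(the major one inside a 3-copy tandem repeat, the minor one at 0.5% of
cancer mitochondrial templates) and one COI allele. Cancer burden maps
linearly to template fractions, each cancer allele contributing
burden × copies/ploidy; burden priors are a design choice (the source
study reports no numeric cancer-cell fractions), defaulting to
uniform [0.4, 0.7] for diseased animals. Clones pick a template
proportionally to these fractions, add Poisson point errors, and with some
probability splice two templates at a uniform crossover.

`reference_cohort()` instantiates, from one seed, a full synthetic
counterpart of a published-style study design: three species, two
independent cancer lineages from the same source species, a South American
and a European subgroup of the focal lineage (the European one carrying
the near-duplicate extra nuclear allele and half its carriers having lost
the minor heteroplasmic allele), mitochondrial replacement in two Chilean
carriers, two Chilean samples with non-lineage neoplasia, and extended
normal panels for the SNP assay. Individual IDs mirror the study design so
reports are recognisable; all sequences are synthetic.

What the generator does *not* emulate bounds what green tests show about
real data: there is no within-tumour evolution beyond the fixed
near-duplicate copies, no nuclear copies of mitochondrial DNA (numts,
which can mimic heteroplasmy and are handled only as a report caveat), no
alignment error (inputs are consumed pre-aligned), no primer bias or
amplification competition beyond the linear template-fraction model, and
real allele-frequency spectra are richer than a Dirichlet over a finite
pool. In particular the linear model cannot make a 0.5% template allele
both reliably cloneable and <1% by qPCR at once; in the synthetic study
the minor heteroplasmic allele is a qPCR-only detection, which the
heteroplasmy logic supports by design.

## Numerical and procedural choices

* Determinism: every simulator takes an explicit seed, restores the
  caller's RNG state, and derives child seeds below 2^31; identical seeds
  reproduce cohorts byte for byte.
* Tie-breaks are stated and deterministic: dedupe orders by count then
  sequence; singleton absorption prefers closer, then higher-support, then
  lexicographically smaller alleles; the chi-square scan takes the
  smallest best split.
* Negative NJ branch lengths (noise artifacts) are clamped to zero;
  midpoint rooting on an all-zero-length tree warns that the root is
  arbitrary; Jukes-Cantor distances at p ≥ 0.75 are undefined and returned
  as `NaN` with a warning.
* Coordinates are 0-based half-open wherever intervals are reported.
* Problem sizes used by the validation suite — 100 clone sets, 50 cohorts
  of 60 animals, 200 recombinants, 40 tree replicates — match the scale of
  the study design while keeping the whole suite in the order of a minute
  on one core.

## Worked example

```{r example}
ref <- reference_cohort(seed = 1)
clones <- reference_clone_sets(ref, seed = 2)
run <- run_pipeline(
  clones, ref$sheet, btn_config(loci = ref$loci, seed = 2),
  qpcr_plate = reference_qpcr_plate(ref, seed = 3),
  kasp_records = reference_kasp(ref, seed = 4),
  mito_parents = list(mtCR = parental_pair(
    ref$lineages$btn2_sa$mito_parents$mtCR$female,
    ref$lineages$btn2_sa$mito_parents$mtCR$male)))
run
run$profile[run$profile$n_diseased > 2,
            c("locus", "label", "n_diseased", "family")]
subset(run$classification, diagnosis == "cancer",
       c(id, species, lineage_loci, classification))
run$breakpoints[["mtCR:A"]]
```

## Known limitations

With very small normal panels the absent-from-normals filter is weak, and
profile entries supported by exactly two anomalous carriers can still be
identity-by-state coincidences; they are reported with their carrier
counts so the analyst can weigh them, and the multi-locus concordance rule
keeps them out of the final classification. Cohorts with fewer than two
diseased carriers cannot, by construction, yield a shared-allele profile.
The breakpoint scan assumes exactly one crossover; alleles with two or
more true crossovers are reported `complex` rather than resolved. The
qPCR model does not estimate absolute cancer-cell counts, and a
repeat-bearing locus in particular cannot be used for that purpose.
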