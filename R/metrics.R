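# Parameter-recovery metrics.  Each function plants truth with the
# synthetic generator, runs the corresponding analysis stage, and scores
# recovery.  They power both the validation vignette and the acceptance
# checks; sizes are arguments so callers choose their compute budget.

#' Remove a lineage's founder alleles from the contemporary pools
#'
#' A cancer lineage's founder animal lived in the (possibly distant) past;
#' treating its exact alleles as unsampled in today's normal population
#' reproduces the observation that cancer-associated alleles are found in
#' no normal individual.
#'
#' @param pools Output of [make_species_pools()].
#' @param lineage A `cancer_lineage`.
#' @return The pools with the founder's nuclear allele sequences removed.
#' @export
privatize_founders <- function(pools, lineage) {
  sp <- lineage$source_species
  for (lc in names(lineage$nuclear)) {
    pl <- pools[[sp]]$loci[[lc]]
    keep <- !(pl$alleles %in% lineage$nuclear[[lc]]$sequence)
    pl$alleles <- pl$alleles[keep]
    pl$freqs <- pl$freqs[keep] / sum(pl$freqs[keep])
    pools[[sp]]$loci[[lc]] <- pl
  }
  pools
}

#' Clone-curation recovery over replicate clone sets
#'
#' Plants a diseased individual (host heterozygote plus a tetraploid cancer
#' genotype, four templates), samples a clone set, curates it, and scores
#' the curated calls against the templates that were actually sampled.  A
#' call matches a planted allele within `tolerance` differences (residual
#' single-site PCR error; downstream lineage logic uses the same
#' near-match radius).  Precision is scored over the presented alleles —
#' multi-clone calls, following the rule that a presented allele is found
#' in at least two clones — while recall counts a planted allele as
#' detected when any call (including a flagged low-confidence singleton)
#' matches it.
#'
#' @param n_sets Replicate clone sets.
#' @param n_clones Clones per set.
#' @param error_rate,chimera_rate Clone noise parameters.
#' @param burden Cancer template fraction of the planted individual.
#' @param tolerance Match radius in differences.
#' @param seed Integer seed.
#' @return List: precision, recall, n_sets.
#' @export
curation_recovery <- function(n_sets = 100, n_clones = 12,
                              error_rate = 0.001, chimera_rate = 0.1,
                              burden = 0.5, tolerance = 1, seed = 1) {
  loci <- list(EF1a = locus_spec("EF1a", "nuclear", 516, 2))
  pools <- make_species_pools(2, loci, divergence = 0.05,
                              seed = child_seed(seed, 1))
  lineage <- make_cancer_lineage(pools, "sp1", ploidy = 4,
                                 seed = child_seed(seed, 2))
  pools <- privatize_founders(pools, lineage)
  tp_pres <- fp <- tp <- fn <- 0L
  for (r in seq_len(n_sets)) {
    ind <- make_cohort(pools, n = 1, species = "sp2", prevalence = 1,
                       lineage = lineage, burden_range = c(burden, burden),
                       distinct_host_alleles = TRUE,
                       seed = child_seed(seed, 10 + 2 * r))$individuals[[1]]
    cs <- sample_clones(ind, "EF1a", n_clones, error_rate, chimera_rate,
                        seed = child_seed(seed, 11 + 2 * r))
    calls <- call_alleles(cs, loci$EF1a)
    tmpl <- ind$templates$EF1a
    sampled <- tmpl$sequence[tmpl$label %in% unique(cs$truth$template)]
    presented <- calls$sequence[!calls$singleton]
    hit <- vapply(presented,
                  function(s) min(hamming_to_all(s, sampled)) <= tolerance,
                  logical(1))
    found <- vapply(sampled,
                    function(s) min(hamming_to_all(s, calls$sequence)) <= tolerance,
                    logical(1))
    tp <- tp + sum(found)
    fn <- fn + sum(!found)
    tp_pres <- tp_pres + sum(hit)
    fp <- fp + sum(!hit)
  }
  list(precision = tp_pres / (tp_pres + fp), recall = tp / (tp + fn),
       n_sets = n_sets)
}

#' Exact lineage-recovery rate over replicate cohorts
#'
#' Simulates cohorts with a planted cancer lineage, runs clone curation and
#' shared-allele detection, and scores a replicate as recovered when the
#' detected cancer-associated allele set equals the planted founder set
#' exactly.
#'
#' @param n_cohorts Replicate cohorts.
#' @param n Individuals per cohort.
#' @param prevalence Disease prevalence.
#' @param n_clones Clones per individual.
#' @param error_rate,chimera_rate Clone noise parameters.
#' @param radius Near-match radius of the detection stage.
#' @param seed Integer seed.
#' @return List: rate (fraction of cohorts with exact recovery), n_cohorts.
#' @export
lineage_recovery_rate <- function(n_cohorts = 50, n = 60, prevalence = 0.1,
                                  n_clones = 12, error_rate = 0.001,
                                  chimera_rate = 0.05, radius = 1,
                                  seed = 1) {
  loci <- list(EF1a = locus_spec("EF1a", "nuclear", 516, 2))
  ok <- 0L
  for (r in seq_len(n_cohorts)) {
    base <- child_seed(seed, 100 * r)
    pools <- make_species_pools(2, loci, divergence = 0.05,
                                seed = child_seed(base, 1))
    lineage <- make_cancer_lineage(pools, "sp1", ploidy = 4,
                                   seed = child_seed(base, 2))
    pools <- privatize_founders(pools, lineage)
    cohort <- make_cohort(pools, n = n, species = "sp2",
                          prevalence = prevalence, lineage = lineage,
                          seed = child_seed(base, 3))
    calls <- vector("list", n)
    for (i in seq_len(n)) {
      cs <- sample_clones(cohort$individuals[[i]], "EF1a", n_clones,
                          error_rate, chimera_rate,
                          seed = child_seed(base, 10 + i))
      calls[[i]] <- call_alleles(cs, loci$EF1a)
    }
    genotypes <- build_genotypes(calls, cohort_sample_sheet(cohort))
    prof <- find_shared_cancer_alleles(genotypes, "EF1a", radius)
    if (setequal(prof$sequence, lineage$nuclear$EF1a$sequence)) ok <- ok + 1L
  }
  list(rate = ok / n_cohorts, n_cohorts = n_cohorts)
}

#' Breakpoint-recovery rate over synthetic recombinants
#'
#' Splices a female/male parental pair at a random crossover between
#' interior informative sites and checks that the maximum chi-square scan
#' calls a single crossover whose reported interval contains the true
#' splice point.
#'
#' @param n Replicates.
#' @param length Sequence length.
#' @param n_diff Substitutions between the parents (informative sites).
#' @param seed Integer seed.
#' @return List: rate, n.
#' @export
breakpoint_recovery_rate <- function(n = 200, length = 600, n_diff = 40,
                                     seed = 1) {
  ok <- 0L
  with_seed(seed, {
    for (r in seq_len(n)) {
      f <- random_seq(length)
      m <- mutate_seq(f, n_diff)
      pp <- parental_pair(f, m)
      inf <- pp$informative
      # crossover between interior informative sites: recombinants with the
      # switch outside the informative span are undetectable in principle
      lo <- inf[2]
      hi <- inf[length(inf) - 1]
      cx <- sample(lo:(hi - 1), 1)           # 1-based splice point
      q <- splice_seqs(f, m, cx)
      bc <- find_breakpoint(q, pp)
      if (bc$verdict == "single-crossover" &&
          bc$interval[1] <= cx && cx < bc$interval[2]) {
        ok <- ok + 1L
      }
    }
  })
  list(rate = ok / n, n = n)
}

#' Species-monophyly recovery rate of neighbor-joining trees
#'
#' Generates species pools at roughly five-fold inter- versus intra-species
#' divergence, builds the NJ tree of all alleles, midpoint-roots it, and
#' checks that every species' alleles form a clade.
#'
#' @param n_reps Replicates.
#' @param n_species Species per replicate.
#' @param n_alleles Alleles per species.
#' @param divergence Inter-species divergence (substitutions/site).
#' @param intra_mutations Mean private substitutions per allele.
#' @param seed Integer seed.
#' @return List: rate, n_reps.
#' @export
nj_monophyly_rate <- function(n_reps = 40, n_species = 3, n_alleles = 5,
                              divergence = 0.075, intra_mutations = 2,
                              seed = 1) {
  loci <- list(L1 = locus_spec("L1", "nuclear", 500, 2))
  ok <- 0L
  for (r in seq_len(n_reps)) {
    pools <- make_species_pools(n_species, loci, divergence = divergence,
                                n_alleles = n_alleles,
                                intra_mutations = intra_mutations,
                                seed = child_seed(seed, r))
    seqs <- do.call(c, unname(lapply(pools, function(p) {
      stats::setNames(p$loci$L1$alleles,
                      paste(p$species, seq_along(p$loci$L1$alleles), sep = "-"))
    })))
    tr <- midpoint_root(nj_tree(alignment_distances(seqs, "JC")))
    mono <- all(vapply(pools, function(p) {
      tips <- grep(paste0("^", p$species, "-"), tr$tip.label, value = TRUE)
      ape::is.monophyletic(tr, tips)
    }, logical(1)))
    if (mono) ok <- ok + 1L
  }
  list(rate = ok / n_reps, n_reps = n_reps)
}

#' qPCR burden monotonicity (rank correlation)
#'
#' Simulates one individual over a burden grid at fixed noise and reports
#' the Spearman correlation between the planted burden and the measured
#' cancer-allele fraction at the first nuclear locus.
#'
#' @param burdens Burden grid.
#' @param sdlog Lognormal copy-number noise.
#' @param seed Integer seed.
#' @return List: rank_correlation, n.
#' @export
qpcr_monotonicity <- function(burdens = seq(0.05, 0.95, by = 0.05),
                              sdlog = 0.1, seed = 1) {
  loci <- list(EF1a = locus_spec("EF1a", "nuclear", 516, 2))
  pools <- make_species_pools(2, loci, divergence = 0.05,
                              seed = child_seed(seed, 1))
  lineage <- make_cancer_lineage(pools, "sp1", ploidy = 4,
                                 seed = child_seed(seed, 2))
  pools <- privatize_founders(pools, lineage)
  assay <- default_qpcr_assay(lineage)
  fr <- numeric(length(burdens))
  for (i in seq_along(burdens)) {
    ind <- make_cohort(pools, n = 1, species = "sp2", prevalence = 1,
                       lineage = lineage,
                       burden_range = rep(burdens[i], 2),
                       distinct_host_alleles = TRUE,
                       seed = child_seed(seed, 10 + i))$individuals[[1]]
    plate <- simulate_qpcr(ind, assay, seed = child_seed(seed, 100 + i),
                           sdlog = sdlog)
    tab <- allele_fraction_table(plate)
    fr[i] <- tab$fraction[tab$locus == "EF1a"][1]
  }
  list(rank_correlation = stats::cor(burdens, fr, method = "spearman"),
       n = length(burdens))
}
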