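# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# Memoized synthetic reference study plus derived tables.
get_reference <- function(seed = 42) {
  key <- paste0("ref", seed)
  if (is.null(fixture_env[[key]])) {
    ref <- reference_cohort(seed)
    fixture_env[[key]] <- list(
      ref = ref,
      plate = reference_qpcr_plate(ref, seed = seed + 1),
      kasp = reference_kasp(ref, seed = seed + 2))
  }
  fixture_env[[key]]
}

# A small two-species pool + lineage + diseased individual, for clone tests.
get_small_world <- function(seed = 7) {
  key <- paste0("world", seed)
  if (is.null(fixture_env[[key]])) {
    loci <- list(EF1a = locus_spec("EF1a", "nuclear", 516, 2))
    pools <- make_species_pools(2, loci, divergence = 0.05, seed = seed)
    lineage <- make_cancer_lineage(pools, "sp1", ploidy = 4, seed = seed + 1)
    pools <- privatize_founders(pools, lineage)
    fixture_env[[key]] <- list(loci = loci, pools = pools, lineage = lineage)
  }
  fixture_env[[key]]
}

# Random aligned sequence pair at given divergence (uses current RNG).
random_pair <- function(len = 200, n_diff = 10) {
  a <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  chars <- strsplit(a, "")[[1]]
  pos <- sample.int(len, n_diff)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  list(a = a, b = paste(chars, collapse = ""))
}
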