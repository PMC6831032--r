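# Clone curation: deduplication, singleton collapse, chimera discard, and
# the composed caller, checked against planted truth and brute-force
# oracles.

ef1a <- suppressWarnings(locus_spec("EF1a", "nuclear", 60, 2))  # short toy locus

# deterministic toy sequences; flip_at() always changes the base (next
# letter in A->C->G->T->A), so listed positions are guaranteed differences
base <- paste(rep(c("A", "C", "G", "T"), 15), collapse = "")
flip_at <- function(s, pos) {
  ring <- c(A = "C", C = "G", G = "T", T = "A")
  for (p in pos) substr(s, p, p) <- ring[[substr(s, p, p)]]
  s
}
alleleA <- base
b_sites <- c(5, 12, 20, 27, 35, 42, 50, 57)
alleleB <- flip_at(base, b_sites)

test_that("dedupe counts, orders, and is permutation-invariant", {
  cs <- clone_set(c(rep(alleleA, 5), rep(alleleB, 3)), "i1", "EF1a")
  u <- dedupe_clones(cs)
  expect_equal(u$count, c(5L, 3L))
  expect_equal(sum(u$count), 8L)
  expect_setequal(u$sequence, c(alleleA, alleleB))

  one <- clone_set(rep(alleleA, 4), "i1", "EF1a")
  expect_equal(nrow(dedupe_clones(one)), 1L)

  for (r in 1:5) {
    set.seed(r)
    shuf <- clone_set(sample(c(rep(alleleA, 5), rep(alleleB, 3))), "i1", "EF1a")
    expect_identical(dedupe_clones(shuf), u)
  }

  ragged <- list(individual_id = "i1", locus = "EF1a",
                 clones = c(alleleA, substr(alleleA, 1, 10)))
  class(ragged) <- "clone_set"
  expect_error(dedupe_clones(ragged), "unequal")
})

test_that("singletons are absorbed within the locus threshold, retained beyond", {
  v2 <- flip_at(alleleA, c(7, 14))   # distance 2 from A, far from B
  expect_equal(oracle_hamming(v2, alleleA), 2L)
  cs <- clone_set(c(rep(alleleA, 3), rep(alleleB, 2), v2), "i1", "EF1a")
  out <- collapse_singletons(dedupe_clones(cs), ef1a)
  expect_equal(nrow(out), 2L)
  expect_equal(out$support[out$sequence == alleleA], 4L)  # 3 + absorbed
  expect_identical(out$absorbed[out$sequence == alleleA][[1]], v2)

  v3 <- flip_at(alleleA, c(7, 14, 23))  # distance 3: beyond the threshold
  cs3 <- clone_set(c(rep(alleleA, 3), rep(alleleB, 2), v3), "i1", "EF1a")
  out3 <- collapse_singletons(dedupe_clones(cs3), ef1a)
  expect_equal(nrow(out3), 3L)
  expect_true(v3 %in% out3$sequence)
  expect_true(out3$singleton[out3$sequence == v3])
})

test_that("chimeric singletons are discarded; multi-crossover ones retained", {
  # splice after site 30: A at informative sites 5..27, B at 35..57
  chim <- flip_at(alleleA, b_sites[b_sites > 30])
  expect_equal(oracle_hamming(chim, alleleA), 4L)  # beyond collapse radius
  cs <- clone_set(c(rep(alleleA, 3), rep(alleleB, 2), chim), "i1", "EF1a")
  out <- call_alleles(cs, ef1a)
  expect_equal(nrow(out), 2L)
  expect_identical(attr(out, "discarded_chimeras"), chim)
  expect_true(oracle_chimera(chim, alleleA, alleleB))

  # alternating A/A/B/B/A/A/B/B mosaic needs more than one crossover
  twox <- flip_at(alleleA, c(20, 27, 50, 57))
  expect_false(oracle_chimera(twox, alleleA, alleleB))
  expect_false(oracle_chimera(twox, alleleB, alleleA))
  cs2 <- clone_set(c(rep(alleleA, 3), rep(alleleB, 2), twox), "i1", "EF1a")
  out2 <- call_alleles(cs2, ef1a)
  expect_equal(nrow(out2), 3L)
  expect_length(attr(out2, "discarded_chimeras"), 0L)
})

test_that("chimera test matches the exhaustive oracle on random instances", {
  set.seed(99)
  n_checked <- 0L
  for (r in 1:120) {
    pr <- random_pair(len = 80, n_diff = sample(4:10, 1))
    L <- 80
    q <- if (r %% 3 == 0) {
      # true single-crossover splice
      k <- sample(10:70, 1)
      paste0(substr(pr$a, 1, k), substr(pr$b, k + 1, L))
    } else if (r %% 3 == 1) {
      # random mosaic (usually needs >1 crossover)
      ca <- strsplit(pr$a, "")[[1]]; cb <- strsplit(pr$b, "")[[1]]
      pick <- sample(c(TRUE, FALSE), L, replace = TRUE)
      paste(ifelse(pick, ca, cb), collapse = "")
    } else {
      # a parent with an extra private mutation
      flip_at(pr$a, sample(L, 1))
    }
    got <- mytBTN:::is_single_crossover(q, pr$a, pr$b)
    want <- oracle_chimera(q, pr$a, pr$b)
    expect_identical(got, want)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 100L)
})

test_that("call_alleles recovers planted genotypes and conserves clones", {
  w <- get_small_world()
  # heterozygous normal at low error: exactly 2 calls
  normal <- make_cohort(w$pools, n = 1, species = "sp2", prevalence = 0,
                        distinct_host_alleles = TRUE,
                        seed = 81)$individuals[[1]]
  cs <- sample_clones(normal, "EF1a", 8, error_rate = 1e-4,
                      chimera_rate = 0, seed = 82)
  calls <- call_alleles(cs, w$loci$EF1a)
  expect_lte(nrow(calls), 3L)
  expect_setequal(
    intersect(calls$sequence, normal$templates$EF1a$sequence),
    unique(cs$clones[cs$truth$n_errors == 0]))

  # diseased host+cancer, 12 clones: calls cover the sampled planted alleles
  ind <- make_cohort(w$pools, n = 1, species = "sp2", prevalence = 1,
                     lineage = w$lineage, burden_range = c(0.5, 0.5),
                     distinct_host_alleles = TRUE, seed = 83)$individuals[[1]]
  cs2 <- sample_clones(ind, "EF1a", 12, error_rate = 1e-4,
                       chimera_rate = 0.02, seed = 84)
  calls2 <- call_alleles(cs2, w$loci$EF1a)
  sampled <- ind$templates$EF1a$sequence[
    ind$templates$EF1a$label %in% cs2$truth$template]
  for (s in sampled) {
    expect_lte(min(vapply(calls2$sequence, hamming_distance, integer(1), s)), 2)
  }

  # clone-count conservation: supports + discarded singletons = input clones
  expect_equal(sum(calls2$support) + length(attr(calls2, "discarded_chimeras")),
               length(cs2$clones))

  expect_error(call_alleles(list(clones = character(0)), w$loci$EF1a))
})

test_that("curation is idempotent on curated alleles", {
  w <- get_small_world()
  ind <- make_cohort(w$pools, n = 1, species = "sp2", prevalence = 1,
                     lineage = w$lineage, burden_range = c(0.5, 0.5),
                     distinct_host_alleles = TRUE, seed = 91)$individuals[[1]]
  cs <- sample_clones(ind, "EF1a", 12, error_rate = 1e-4, seed = 92)
  calls <- call_alleles(cs, w$loci$EF1a)
  # re-feed each call with its support as clone multiplicity
  again <- clone_set(rep(calls$sequence, calls$support), "i", "EF1a")
  calls2 <- call_alleles(again, w$loci$EF1a)
  expect_setequal(calls2$sequence[calls2$support > 1],
                  calls$sequence[calls$support > 1])
})

test_that("curation recovery meets the precision/recall floor (spot check)", {
  rec <- curation_recovery(n_sets = 30, seed = 123)
  expect_gte(rec$precision, 0.95)
  expect_gte(rec$recall, 0.95)
})
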