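# Synthetic cohort generator: determinism, divergence calibration,
# conservation, and the planted-truth bookkeeping the recovery tests rely on.

test_that("species pools are deterministic and hit the requested divergence", {
  loci <- list(L1 = locus_spec("L1", "nuclear", 500, 2))
  p1 <- make_species_pools(3, loci, divergence = 0.05, seed = 11)
  p2 <- make_species_pools(3, loci, divergence = 0.05, seed = 11)
  expect_identical(p1, p2)
  p3 <- make_species_pools(3, loci, divergence = 0.05, seed = 12)
  expect_false(identical(p1, p3))

  # realized mean cross-pool divergence within 30% of 0.05 * 500 = 25 sites
  d12 <- pool_divergence <- mytBTN:::pool_divergence
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    div <- d12(p1[[pair[1]]], p1[[pair[2]]], "L1")
    expect_gt(div, 25 * 0.7)
    expect_lt(div, 25 * 1.3)
  }
})

test_that("zero divergence collapses species onto one shared ancestor set", {
  loci <- list(L1 = locus_spec("L1", "nuclear", 400, 1))
  p <- make_species_pools(2, loci, divergence = 0, intra_mutations = 2,
                          seed = 3)
  # cross-pool distances are at the intra-species scale, not a species gap
  cross <- mytBTN:::pool_divergence(p[[1]], p[[2]], "L1")
  expect_lt(cross, 15)
})

test_that("too-short loci are rejected", {
  loci <- list(tiny = locus_spec("tiny", "nuclear", 49, 0))
  expect_error(make_species_pools(2, loci, seed = 1), "shorter than 50")
})

test_that("cohort prevalence, lineage carriage, and hybrid rate behave", {
  w <- get_small_world()
  cohort <- make_cohort(w$pools, n = 60, species = "sp2", prevalence = 0.1,
                        lineage = w$lineage, seed = 21)
  diag <- vapply(cohort$individuals, function(i) i$diagnosis, character(1))
  expect_gte(sum(diag == "cancer"), 1)
  expect_lte(sum(diag == "cancer"), 15)
  # every diseased individual carries host + lineage alleles: 4 distinct
  # templates at a heterozygous nuclear locus
  for (ind in cohort$individuals[diag == "cancer"]) {
    tm <- ind$templates$EF1a
    expect_setequal(
      tm$sequence[tm$origin == "cancer"], w$lineage$nuclear$EF1a$sequence)
    if (length(unique(ind$nuclear$EF1a)) == 2) {
      expect_equal(nrow(tm), 4)
    }
  }
  # prevalence 0: nobody carries lineage alleles
  c0 <- make_cohort(w$pools, n = 30, species = "sp2", prevalence = 0,
                    lineage = w$lineage, seed = 22)
  for (ind in c0$individuals) {
    expect_false(any(ind$templates$EF1a$origin == "cancer"))
  }
  # hybrid rate: binomial count oracle at n = 400, rate 0.05 -> ~20
  ch <- make_cohort(w$pools, n = 400, species = "sp2", prevalence = 0,
                    hybrid_rate = 0.05, seed = 23)
  nh <- sum(vapply(ch$individuals, function(i) i$is_hybrid, logical(1)))
  expect_gte(nh, qbinom(0.0005, 400, 0.05))
  expect_lte(nh, qbinom(0.9995, 400, 0.05))
  expect_error(make_cohort(list(), n = 5), "empty pool")
})

test_that("clone sampling conserves counts and respects noise settings", {
  w <- get_small_world()
  normal <- make_cohort(w$pools, n = 1, species = "sp2", prevalence = 0,
                        distinct_host_alleles = TRUE,
                        seed = 31)$individuals[[1]]
  cs <- sample_clones(normal, "EF1a", n_clones = 20, error_rate = 0,
                      chimera_rate = 0, seed = 32)
  expect_length(cs$clones, 20)
  expect_equal(length(unique(cs$clones)), 2)  # exactly the two haplotypes
  expect_true(all(unique(cs$clones) %in% normal$templates$EF1a$sequence))

  # determinism
  cs2 <- sample_clones(normal, "EF1a", n_clones = 20, error_rate = 0,
                       chimera_rate = 0, seed = 32)
  expect_identical(cs$clones, cs2$clones)

  # chimera_rate 1 with two templates: clone is a one-crossover splice
  cs3 <- sample_clones(normal, "EF1a", n_clones = 5, error_rate = 0,
                       chimera_rate = 1, seed = 33)
  tm <- normal$templates$EF1a$sequence
  for (k in seq_along(cs3$clones)) {
    q <- cs3$clones[[k]]
    if (q %in% tm) next  # crossover outside the informative span
    expect_true(oracle_chimera(q, tm[1], tm[2], min_side = 1L) ||
                  oracle_chimera(q, tm[2], tm[1], min_side = 1L))
  }
})

test_that("cancer burden weights clone sampling towards cancer templates", {
  w <- get_small_world()
  ind <- make_cohort(w$pools, n = 1, species = "sp2", prevalence = 1,
                     lineage = w$lineage, burden_range = c(0.9, 0.9),
                     seed = 41)$individuals[[1]]
  n_cancer <- 0L
  n_total <- 0L
  for (r in 1:200) {
    cs <- sample_clones(ind, "EF1a", n_clones = 1, error_rate = 0,
                        chimera_rate = 0, seed = 100 + r)
    n_cancer <- n_cancer + sum(cs$truth$origin == "cancer")
    n_total <- n_total + 1L
  }
  expect_gte(n_cancer / n_total, 0.7)
})

test_that("qPCR simulation recovers fractions exactly at zero noise", {
  w <- get_small_world()
  assay <- default_qpcr_assay(w$lineage)
  ind <- make_cohort(w$pools, n = 1, species = "sp2", prevalence = 1,
                     lineage = w$lineage, burden_range = c(0.5, 0.5),
                     distinct_host_alleles = TRUE, seed = 51)$individuals[[1]]
  plate <- simulate_qpcr(ind, assay, seed = 52, sdlog = 0)
  tab <- allele_fraction_table(plate)
  # the assayed allele is one of two founders at copies 2/4: fraction b/2
  expect_equal(tab$fraction[1], 0.25, tolerance = 1e-12)

  # burden 0: allele-specific copies below the 10-copy detection floor
  n0 <- make_cohort(w$pools, n = 1, species = "sp2", prevalence = 0,
                    seed = 53)$individuals[[1]]
  p0 <- simulate_qpcr(n0, assay, seed = 54, sdlog = 0)
  spec <- p0[p0$target != "universal", ]
  expect_true(all(spec$copies < 10))
})

test_that("tandem-repeat copy number inflates the allele-specific fraction", {
  fx <- get_reference()
  tab <- allele_fraction_table(fx$plate)
  d <- tab[tab$allele == "D" & tab$sample == "Ch13", ]
  # burden 0.65, repeat copy number 3: expected fraction ~ 1.9
  expect_gt(d$fraction, 1)
  expect_identical(d$status, "over_unity")
})

test_that("KASP simulation is clean for pure hosts and scales with burden", {
  w <- get_small_world()
  panel <- make_snp_panel(13)
  host <- make_cohort(w$pools, n = 1, species = "sp2", prevalence = 0,
                      seed = 61)$individuals[[1]]
  rec <- simulate_kasp(host, panel, seed = 62, noise_sd = 0)
  expect_true(all(kasp_transform(rec$x, rec$y) == 0))

  # expected y' strictly increasing in burden at zero noise
  yps <- vapply(seq(0.1, 0.9, by = 0.2), function(b) {
    ind <- host
    ind$cancer_burden <- b
    r <- simulate_kasp(ind, panel, seed = 63, noise_sd = 0)
    mean(kasp_transform(r$x, r$y))
  }, numeric(1))
  expect_true(all(diff(yps) > 0))

  # an introgressed heterozygous diagnostic locus reads y' = 0.5 there only
  intro <- host
  intro$introgressed_snp_loci <- 4L
  r <- simulate_kasp(intro, panel, seed = 64, noise_sd = 0)
  yp <- kasp_transform(r$x, r$y)
  expect_equal(yp[4], 0.5)
  expect_true(all(yp[-4] == 0))
})

test_that("cohort writers export sheet, truth and clone FASTA round-trippably", {
  w <- get_small_world()
  cohort <- make_cohort(w$pools, n = 4, species = "sp2", prevalence = 0.5,
                        lineage = w$lineage, seed = 71)
  cs <- sample_clones(cohort$individuals[[1]], "EF1a", 6, seed = 72)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir, clone_sets = list(cs))
  sheet <- read_sample_sheet(file.path(dir, "sample_sheet.tsv"))
  expect_identical(sheet$id, cohort_sample_sheet(cohort)$id)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_length(truth$individuals, 4)
  fasta <- list.files(dir, pattern = "^clones_.*fasta$", full.names = TRUE)
  expect_length(fasta, 1)
  aln <- read_alignment(fasta[1], label_regex = "^(.+)_c([0-9]+)$")
  expect_identical(unname(aln$seqs), unname(cs$clones))
})
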