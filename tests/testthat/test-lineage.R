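# Lineage detection: supernumerary counts, shared cancer-associated
# alleles, near-duplicate families, and lineage identity comparisons.

# toy genotype builder: each allele becomes a support-3 call
toy_genotype <- function(id, seqs, diagnosis = "normal", locus = "EF1a",
                         species = "M. chilensis") {
  calls <- data.frame(sequence = seqs, support = 3L,
                      label = LETTERS[seq_along(seqs)],
                      singleton = FALSE, stringsAsFactors = FALSE)
  attr(calls, "individual_id") <- id
  attr(calls, "locus") <- locus
  g <- list(calls)
  names(g) <- locus
  individual_genotype(id, species, NA, diagnosis, g)
}

# deterministic, mutually distant toy alleles
set.seed(5)
toy_seq <- replicate(10, paste(sample(c("A", "C", "G", "T"), 120,
                                      replace = TRUE), collapse = ""))
names(toy_seq) <- c("E", "F", "G", "H", "I", "J", "K", "L", "M", "N")

test_that("allele counts flag supernumerary nuclear genotypes", {
  g4 <- toy_genotype("Mch41", toy_seq[c("E", "F", "G", "H")], "cancer")
  n <- count_alleles(g4, "EF1a")
  expect_equal(as.integer(n), 4L)
  expect_true(attr(n, "supernumerary"))

  g1 <- toy_genotype("hom", toy_seq["E"])
  n1 <- count_alleles(g1, "EF1a")
  expect_equal(as.integer(n1), 1L)
  expect_false(attr(n1, "supernumerary"))

  # mito loci are exempt (DUI expectation handled separately)
  gm <- toy_genotype("mito3", toy_seq[c("E", "F", "G")], "cancer", "mtCR")
  expect_false(attr(count_alleles(gm, "mtCR", category = "mito"),
                    "supernumerary"))

  expect_error(count_alleles(g1, "H4"), "missing")

  # monotone: adding cancer alleles never clears the flag
  for (k in 3:6) {
    gk <- toy_genotype("x", toy_seq[seq_len(k)], "cancer")
    expect_true(attr(count_alleles(gk, "EF1a"), "supernumerary"))
  }
})

test_that("shared alleles across diseased individuals form the profile", {
  cohort <- list(
    toy_genotype("Mch41", toy_seq[c("E", "F", "G", "H")], "cancer"),
    toy_genotype("Mch42", toy_seq[c("I", "J", "G", "H")], "cancer"),
    toy_genotype("Mch3", toy_seq[c("E", "K")], "normal"),
    toy_genotype("Mch5", toy_seq[c("L", "I")], "normal"))
  prof <- find_shared_cancer_alleles(cohort, "EF1a", 1)
  expect_setequal(prof$sequence, unname(toy_seq[c("G", "H")]))
  expect_equal(prof$n_diseased, c(2L, 2L))
  expect_setequal(prof$supporting[[1]], c("Mch41", "Mch42"))

  # no diseased individuals: empty profile
  empty <- find_shared_cancer_alleles(cohort[3:4], "EF1a", 1)
  expect_equal(nrow(empty), 0L)

  # an allele present in any normal never enters the profile
  cohort2 <- c(cohort, list(toy_genotype("Mch7", toy_seq[c("G", "M")],
                                         "normal")))
  prof2 <- find_shared_cancer_alleles(cohort2, "EF1a", 1)
  expect_setequal(prof2$sequence, unname(toy_seq["H"]))
})

test_that("profile recovery is exact on a planted synthetic cohort", {
  w <- get_small_world()
  cohort <- make_cohort(w$pools, n = 40, species = "sp2", prevalence = 0.15,
                        lineage = w$lineage, seed = 101)
  calls <- lapply(seq_len(40), function(i) {
    cs <- sample_clones(cohort$individuals[[i]], "EF1a", 12,
                        error_rate = 2e-4, chimera_rate = 0.02,
                        seed = 200 + i)
    call_alleles(cs, w$loci$EF1a)
  })
  gen <- build_genotypes(calls, cohort_sample_sheet(cohort))
  prof <- find_shared_cancer_alleles(gen, "EF1a", 1)
  expect_setequal(prof$sequence, w$lineage$nuclear$EF1a$sequence)
})

test_that("near-duplicate profile alleles merge into polyploid families", {
  h <- toy_seq[["H"]]
  hp <- sub(substr(h, 1, 1),
            setdiff(c("A", "C", "G", "T"), substr(h, 1, 1))[1], h)
  prof <- lineage_profile(list(data.frame(
    locus = "EF1a", sequence = c(toy_seq[["G"]], h, hp),
    n_diseased = c(3L, 3L, 2L), label = c("G", "H", "H'"),
    stringsAsFactors = FALSE)))
  m <- merge_near_duplicates(prof, 1)
  expect_equal(m$family[m$label == "H"], m$family[m$label == "H'"])
  expect_false(m$family[m$label == "G"] == m$family[m$label == "H"])
  # radius 0: identity, no merging
  m0 <- merge_near_duplicates(prof, 0)
  expect_equal(length(unique(m0$family)), 3L)
  # all mutually distant: families of size 1
  md <- merge_near_duplicates(prof[1:2, ], 1)
  expect_equal(length(unique(md$family)), 2L)
})

test_that("lineage comparison verdicts: identical, near-identical, distinct", {
  fx <- get_reference()
  lins <- fx$ref$lineages
  prof_of <- function(lin) {
    frames <- lapply(names(lin$nuclear), function(lc) {
      data.frame(locus = lc, sequence = lin$nuclear[[lc]]$sequence,
                 n_diseased = 2L, label = lin$nuclear[[lc]]$label,
                 stringsAsFactors = FALSE)
    })
    lineage_profile(frames)
  }
  sa <- prof_of(lins$btn2_sa)
  eu <- prof_of(lins$btn2_eu)
  b1 <- prof_of(lins$btn1)

  self <- compare_lineages(sa, sa)
  expect_true(all(self$verdict == "identical"))
  expect_true(attr(self, "same_lineage"))

  cmp <- compare_lineages(sa, eu)
  expect_true(attr(cmp, "same_lineage"))
  expect_identical(cmp$verdict[cmp$locus == "EF1a"], "near-identical")
  expect_equal(cmp$listed_differences[cmp$locus == "EF1a"], 1L)

  cmp1 <- compare_lineages(sa, b1)
  expect_true(all(cmp1$verdict == "distinct"))
  expect_false(attr(cmp1, "same_lineage"))

  expect_error(compare_lineages(sa[sa$locus == "EF1a", ],
                                b1[b1$locus == "H4", ]), "no locus")
})

test_that("individual classification separates lineage from non-lineage disease", {
  cohort <- list(
    toy_genotype("d1", toy_seq[c("E", "F", "G", "H")], "cancer"),
    toy_genotype("d2", toy_seq[c("I", "J", "G", "H")], "cancer"),
    toy_genotype("d3", toy_seq[c("K", "L")], "cancer"),  # conventional cancer
    toy_genotype("n1", toy_seq[c("E", "K")], "normal"))
  prof <- find_shared_cancer_alleles(cohort, "EF1a", 1)
  cls <- classify_individuals(cohort, prof, 1)
  expect_identical(cls$classification,
                   c("lineage-positive", "lineage-positive",
                     "non-lineage neoplasia", "normal"))
  pm <- presence_matrix(cohort, prof, 1)
  expect_equal(dim(pm), c(4L, 2L))
  expect_true(all(pm[1:2, ]))
  expect_false(any(pm[3:4, ]))
})
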