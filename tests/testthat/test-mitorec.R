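# Mitochondrial recombination: breakpoint scanning against brute-force
# split-scan and chi-square oracles, heteroplasmy bookkeeping, and
# tandem-repeat detection.

test_that("non-recombinant and uninformative queries are called correctly", {
  set.seed(71)
  f <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  chars <- strsplit(f, "")[[1]]
  pos <- sample(400, 30)
  for (p in pos) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  m <- paste(chars, collapse = "")
  pp <- parental_pair(f, m)
  expect_length(pp$informative, 30)

  bf <- find_breakpoint(f, pp)
  expect_identical(bf$verdict, "non-recombinant")
  expect_identical(bf$segments$parent, "female")
  bm <- find_breakpoint(m, pp)
  expect_identical(bm$segments$parent, "male")

  # one discordant informative site: still non-recombinant (noise floor)
  q1 <- f
  substr(q1, pos[1], pos[1]) <- substr(m, pos[1], pos[1])
  expect_identical(find_breakpoint(q1, pp)$verdict, "non-recombinant")

  # fewer than 4 informative sites: uninformative
  short_m <- f
  substr(short_m, 5, 5) <- setdiff(c("A","C","G","T"), substr(f, 5, 5))[1]
  expect_identical(find_breakpoint(f, parental_pair(f, short_m))$verdict,
                   "uninformative")
})

test_that("planted crossovers are localized and label-swap symmetric", {
  set.seed(72)
  for (r in 1:50) {
    f <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
               collapse = "")
    chars <- strsplit(f, "")[[1]]
    pos <- sort(sample(500, 40))
    for (p in pos) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
    m <- paste(chars, collapse = "")
    pp <- parental_pair(f, m)
    cx <- sample(pos[3]:(pos[38] - 1), 1)
    q <- paste0(substr(f, 1, cx), substr(m, cx + 1, 500))

    bc <- find_breakpoint(q, pp)
    expect_identical(bc$verdict, "single-crossover")
    expect_identical(bc$segments$parent, c("female", "male"))
    expect_lte(bc$interval[1], cx)
    expect_gt(bc$interval[2], cx)

    # the scan statistic equals the brute-force maximum
    expect_equal(bc$chi_square, oracle_split_scan(q, f, m))

    # swapping the parental labels mirrors the assignment
    swapped <- find_breakpoint(q, parental_pair(m, f))
    expect_identical(swapped$verdict, "single-crossover")
    expect_identical(swapped$segments$parent, c("male", "female"))
    expect_equal(swapped$interval, bc$interval)
  }
})

test_that("chi-square helper matches stats::chisq.test on random tables", {
  set.seed(73)
  for (r in 1:100) {
    tb <- sample(0:12, 4, replace = TRUE)
    expect_equal(mytBTN:::chisq2x2(tb[1], tb[2], tb[3], tb[4]),
                 oracle_chisq(tb[1], tb[2], tb[3], tb[4]))
  }
})

test_that("distinct planted crossover points yield disjoint intervals", {
  fx <- get_reference()
  lin <- fx$ref$lineages$btn2_sa
  pp <- parental_pair(lin$mito_parents$mtCR$female,
                      lin$mito_parents$mtCR$male)
  bc_c <- find_breakpoint(lin$mito$mtCR$sequence[1], pp)  # minor allele
  bc_d <- find_breakpoint(lin$mito$mtCR$sequence[2], pp)  # major allele
  expect_identical(bc_c$verdict, "single-crossover")
  expect_identical(bc_d$verdict, "single-crossover")
  truth <- lin$truth$crossovers$mtCR
  expect_true(bc_c$interval[1] <= truth[1] && truth[1] < bc_c$interval[2])
  expect_true(bc_d$interval[1] <= truth[2] && truth[2] < bc_d$interval[2])
  expect_lte(bc_c$interval[2], bc_d$interval[1])  # non-overlapping
})

test_that("breakpoint recovery rate meets the floor (spot check)", {
  r <- breakpoint_recovery_rate(n = 50, seed = 74)
  expect_gte(r$rate, 0.95)
})

test_that("heteroplasmy report flags presence, loss and replacement", {
  fx <- get_reference()
  ref <- fx$ref
  plate <- fx$plate
  tab <- allele_fraction_table(plate)

  # genotypes from planted truth at the mito loci (clone evidence)
  gens <- lapply(ref$individuals, function(ind) {
    calls <- lapply(c("mtCR", "mtCOI"), function(lc) {
      tm <- ind$templates[[lc]]
      out <- data.frame(sequence = tm$sequence, support = 3L,
                        label = tm$label, singleton = FALSE,
                        stringsAsFactors = FALSE)
      attr(out, "locus") <- lc
      attr(out, "individual_id") <- ind$id
      out
    })
    names(calls) <- c("mtCR", "mtCOI")
    individual_genotype(ind$id, ind$species, ind$site,
                        if (ind$diagnosis == "cancer") "cancer" else "normal",
                        calls)
  })
  lin <- ref$lineages$btn2_sa
  prof <- lineage_profile(list(
    data.frame(locus = "mtCR", sequence = lin$mito$mtCR$sequence,
               n_diseased = 3L, label = lin$mito$mtCR$label,
               stringsAsFactors = FALSE),
    data.frame(locus = "mtCOI", sequence = lin$mito$mtCOI$sequence,
               n_diseased = 3L, label = lin$mito$mtCOI$label,
               stringsAsFactors = FALSE)))
  refs <- list(
    "M. chilensis" = list(mtCOI = ref$pools[["M. chilensis"]]$loci$mtCOI$alleles),
    "M. trossulus" = list(mtCOI = ref$pools[["M. trossulus"]]$loci$mtCOI$alleles))

  rep_ <- assess_heteroplasmy(gens, prof, fractions = tab,
                              species_refs = refs,
                              host_species = "M. chilensis",
                              source_species = "M. trossulus")
  # the trossulus-derived mtCOI allele is not a host replacement
  expect_false(any(rep_$replacement[rep_$locus == "mtCOI"]))
  # the chilensis-derived replacement mitogenome of the Chilean carriers is
  qprof <- lineage_profile(list(data.frame(
    locus = "mtCOI",
    sequence = ref$lineages$btn2_q$mito$mtCOI$sequence,
    n_diseased = 2L, label = "Q", stringsAsFactors = FALSE)))
  rep_q <- assess_heteroplasmy(gens, qprof, species_refs = refs,
                               host_species = "M. chilensis",
                               source_species = "M. trossulus")
  expect_true(all(rep_q$replacement))
  # diseased M. chilensis carry both control-region alleles: heteroplasmic
  mch <- rep_[rep_$id == "Mch41", ]
  expect_true(all(mch$present[mch$locus == "mtCR"]))
  expect_true(all(mch$heteroplasmic))
  # C-loss carriers: C absent while D persists
  ch5 <- rep_[rep_$id == "Ch5" & rep_$locus == "mtCR", ]
  expect_false(ch5$present[ch5$allele == "C"])
  expect_true(ch5$loss[ch5$allele == "C"])
  expect_true(ch5$present[ch5$allele == "D"])
  # normals contribute no rows (diseased only)
  expect_false(any(rep_$id %in% c("Mch3", "HO9")))
})

test_that("tandem repeats are found head-to-tail and sized from qPCR excess", {
  set.seed(75)
  unit <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                collapse = "")
  flank <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
  three <- paste0(flank, strrep(unit, 3), flank)
  rep3 <- detect_tandem_repeat(three, unit)
  expect_true(rep3$junction_found)
  expect_equal(rep3$copies_in_sequence, 3L)

  single <- paste0(flank, unit, flank)
  rep1 <- detect_tandem_repeat(single, unit)
  expect_false(rep1$junction_found)
  expect_equal(rep1$copies_in_sequence, 1L)

  # a 150% allele fraction at ~50% true burden implies ~3 repeat copies
  est <- detect_tandem_repeat(three, unit, qpcr_fraction = 1.5,
                              template_fraction = 0.5)
  expect_equal(est$copies_from_qpcr, 3)

  expect_error(detect_tandem_repeat(three, substr(unit, 1, 10)),
               "shorter than 20")
})
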