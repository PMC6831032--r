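# Synthetic reference study.  Deterministically (given one seed) rebuilds a
# cohort with the structure of the published Mytilus BTN2 study design: three
# species pools, two independent transmissible cancer lineages arising in
# M. trossulus, a South American and a European subgroup of the focal
# lineage (the European one carrying a one-substitution second copy of the
# second nuclear allele), mitochondrial control-region female/male
# recombinants with a tandem repeat on the major allele, heteroplasmy loss
# in half of the European carriers, mitochondrial replacement in the Chilean
# carriers, and two Chilean samples with non-lineage neoplasia.  All
# sequences are synthetic; individual IDs mirror the study design so that
# reports are recognisable.  Planted truth is retained throughout.

# Derive a lineage variant: add a one-substitution near-duplicate of the
# last allele at `locus` (a true polyploid second copy).
add_near_duplicate <- function(lineage, locus, label) {
  df <- lineage$nuclear[[locus]]
  n <- nrow(df)
  df$copies[n] <- df$copies[n] - 1
  df <- rbind(df, data.frame(sequence = mutate_seq(df$sequence[n], 1),
                             copies = 1, label = label,
                             stringsAsFactors = FALSE))
  lineage$nuclear[[locus]] <- df
  lineage
}

drop_mito_allele <- function(lineage, locus, label) {
  df <- lineage$mito[[locus]]
  df <- df[df$label != label, , drop = FALSE]
  df$fraction <- df$fraction / sum(df$fraction)
  lineage$mito[[locus]] <- df
  lineage
}

replace_mito_allele <- function(lineage, locus, sequence, label) {
  lineage$mito[[locus]] <- data.frame(
    sequence = sequence, fraction = 1, label = label, repeat_copies = 1,
    crossover = NA_integer_, stringsAsFactors = FALSE)
  lineage
}

# Remove specific allele sequences from a pool (founder genotypes are
# treated as unsampled in the contemporary normal population).
remove_pool_alleles <- function(pools, species, locus, seqs) {
  pl <- pools[[species]]$loci[[locus]]
  keep <- !(pl$alleles %in% seqs)
  pl$alleles <- pl$alleles[keep]
  pl$freqs <- pl$freqs[keep] / sum(pl$freqs[keep])
  pools[[species]]$loci[[locus]] <- pl
  pools
}

#' Synthetic reference cohort emulating a multi-species field-study design
#'
#' Builds, from one seed, the full synthetic counterpart of the study: the
#' species pools, the two cancer lineages (the focal lineage and an
#' independent earlier one from the same source species), per-individual
#' genotypes for the sequenced cohort, and the extended normal panels for
#' the SNP assay.  Cancer template fractions (burdens) are fixed per
#' individual in [0.4, 0.7] ("high levels" of cancer DNA, with no numeric
#' fractions published); the minor control-region allele is 0.5% of cancer
#' mitochondrial templates, and the major allele sits in a 3-copy tandem
#' repeat.
#'
#' @param seed Integer seed; the cohort structure (who is diseased, who
#'   carries which lineage variant) is fixed, only the sequences and noise
#'   realisations vary with the seed.
#' @return A `btn_reference` list: pools, lineages, individuals, sample
#'   sheet, SNP-panel individuals and sheet, panel definition and qPCR
#'   assay.
#' @export
reference_cohort <- function(seed = 1) {
  loci <- default_loci()
  with_seed(seed, {
    D <- matrix(c(0, .05, .05,
                  .05, 0, .02,
                  .05, .02, 0), 3, 3)
    # host loci are highly polymorphic in wild mussels: large allele pools
    # with uneven frequencies keep identical-by-state sharing between
    # individuals rare, as observed at these loci
    pools <- make_species_pools(
      3, loci, divergence = D, n_alleles = 40, freq_shape = 2,
      male_loci = "mtCR",
      species_names = c("M. trossulus", "M. chilensis", "M. edulis"))

    btn2 <- make_cancer_lineage(
      pools, "M. trossulus", ploidy = 4, hprime = FALSE,
      mito_c_fraction = 0.005, repeat_copies = 3,
      labels = list(EF1a = c("G", "H"), H4 = c("RM", "KNS"),
                    mtCR = c("C", "D"), mtCOI = "B"))

    # the independent earlier lineage, from a different founder: draw from a
    # pool with the focal founders removed so the two never share alleles
    pools_b1 <- pools
    for (lc in names(btn2$nuclear)) {
      pools_b1 <- remove_pool_alleles(pools_b1, "M. trossulus", lc,
                                      btn2$nuclear[[lc]]$sequence)
    }
    btn1 <- make_cancer_lineage(
      pools_b1, "M. trossulus", ploidy = 4, hprime = FALSE,
      recombinant_mito = FALSE, repeat_copies = 1,
      labels = list(EF1a = c("R", "S"), H4 = c("2A", "2B"),
                    mtCR = c("V", "W"), mtCOI = "U"))

    # founder alleles are unsampled in the contemporary normal pools
    for (lin in list(btn2, btn1)) {
      for (lc in names(lin$nuclear)) {
        pools <- remove_pool_alleles(pools, "M. trossulus", lc,
                                     lin$nuclear[[lc]]$sequence)
      }
    }

    btn2_eu <- add_near_duplicate(btn2, "EF1a", "H'")
    btn2_eu_closs <- drop_mito_allele(btn2_eu, "mtCR", "C")
    q_seq <- mutate_seq(sample(pools[["M. chilensis"]]$loci$mtCOI$alleles, 1), 2)
    btn2_q <- replace_mito_allele(btn2, "mtCOI", q_seq, "Q")

    lineages <- list(btn2_sa = btn2, btn2_eu = btn2_eu,
                     btn2_eu_closs = btn2_eu_closs, btn2_q = btn2_q,
                     btn1 = btn1)

    plan <- rbind(
      data.frame(id = c("MW1", "MW2", "MW3", "MW4"),
                 species = "M. trossulus", site = "BC",
                 diagnosis = "normal", burden = 0, lineage = NA,
                 hybrid = NA, stringsAsFactors = FALSE),
      data.frame(id = "MW59", species = "M. trossulus", site = "BC",
                 diagnosis = "normal", burden = 0, lineage = NA,
                 hybrid = "M. edulis", stringsAsFactors = FALSE),
      data.frame(id = c("BCD1", "BCD2"), species = "M. trossulus",
                 site = "BC", diagnosis = "cancer", burden = c(0.50, 0.55),
                 lineage = "btn1", hybrid = NA, stringsAsFactors = FALSE),
      data.frame(id = c("Mch3", "Mch5", "Mch7"), species = "M. chilensis",
                 site = "Argentina", diagnosis = "normal", burden = 0,
                 lineage = NA, hybrid = NA, stringsAsFactors = FALSE),
      data.frame(id = c("Mch23", "Mch41", "Mch42"),
                 species = "M. chilensis", site = "Argentina",
                 diagnosis = "cancer", burden = c(0.45, 0.55, 0.60),
                 lineage = "btn2_sa", hybrid = NA, stringsAsFactors = FALSE),
      data.frame(id = c("Castro26", "Castro52"), species = "M. chilensis",
                 site = "Castro", diagnosis = "cancer",
                 burden = c(0.50, 0.55), lineage = "btn2_q", hybrid = NA,
                 stringsAsFactors = FALSE),
      data.frame(id = c("Castro49", "Castro84"), species = "M. chilensis",
                 site = "Castro", diagnosis = "cancer", burden = 0,
                 lineage = NA, hybrid = NA, stringsAsFactors = FALSE),
      data.frame(id = c("AR5", "AR7", "BA30", "HO8"),
                 species = "M. edulis",
                 site = c("Arcachon", "Arcachon", "Barfleur", "Wadden"),
                 diagnosis = "cancer", burden = c(0.40, 0.45, 0.50, 0.55),
                 lineage = "btn2_eu", hybrid = NA, stringsAsFactors = FALSE),
      data.frame(id = c("Ch5", "Ch13", "LA84", "STBRI43"),
                 species = "M. edulis",
                 site = c("Chausey", "Chausey", "Lannion", "StBrieux"),
                 diagnosis = "cancer", burden = c(0.60, 0.65, 0.50, 0.55),
                 lineage = "btn2_eu_closs", hybrid = NA,
                 stringsAsFactors = FALSE),
      data.frame(id = c("Ch10", "Ch11", "BA12", "BA24", "HO9", "HO19",
                        "STBRI28"),
                 species = "M. edulis",
                 site = c("Chausey", "Chausey", "Barfleur", "Barfleur",
                          "Wadden", "Wadden", "StBrieux"),
                 diagnosis = "normal", burden = 0, lineage = NA, hybrid = NA,
                 stringsAsFactors = FALSE))

    individuals <- list()
    for (i in seq_len(nrow(plan))) {
      individuals[[plan$id[i]]] <- make_individual(
        pools, plan$species[i], plan$id[i], plan$site[i],
        diagnosis = plan$diagnosis[i], burden = plan$burden[i],
        lineage = if (is.na(plan$lineage[i])) NULL else lineages[[plan$lineage[i]]],
        hybrid_donor = if (is.na(plan$hybrid[i])) NULL else plan$hybrid[i],
        distinct_host_alleles = TRUE)
    }

    sheet <- cohort_sample_sheet(
      structure(list(individuals = individuals), class = "sim_cohort"))

    # SNP-assay cohort: the study's assayed cancer/normal samples plus
    # extended normal panels; every 12th extended normal is introgressed at
    # one diagnostic locus (never more than one in this cohort)
    kasp_ids <- c("Mch23", "Mch41", "Mch42", "Mch3", "Mch5", "Mch7",
                  "BA30", "HO8", "Ch5", "Ch13", "LA84", "STBRI43",
                  "HO9", "HO19", "Ch10", "Ch11")
    kasp_individuals <- individuals[kasp_ids]
    ext <- rbind(
      data.frame(id = sprintf("MchN%03d", 1:109), species = "M. chilensis",
                 site = "extended", stringsAsFactors = FALSE),
      data.frame(id = sprintf("EdN%02d", 1:62), species = "M. edulis",
                 site = "extended", stringsAsFactors = FALSE))
    for (i in seq_len(nrow(ext))) {
      kasp_individuals[[ext$id[i]]] <- make_individual(
        pools, ext$species[i], ext$id[i], ext$site[i],
        diagnosis = "normal", distinct_host_alleles = TRUE,
        introgressed_snp_loci = if (i %% 12 == 0) sample.int(13L, 1) else integer(0))
    }
    kasp_sheet <- cohort_sample_sheet(
      structure(list(individuals = kasp_individuals), class = "sim_cohort"))

    structure(
      list(pools = pools, loci = loci, lineages = lineages,
           individuals = individuals, sheet = sheet,
           kasp_individuals = kasp_individuals, kasp_sheet = kasp_sheet,
           panel = make_snp_panel(13),
           assay = default_qpcr_assay(btn2),
           seed = seed),
      class = "btn_reference")
  })
}

#' @export
print.btn_reference <- function(x, ...) {
  cat(sprintf("<synthetic reference study: %d sequenced individuals, %d SNP-assay samples>\n",
              length(x$individuals), length(x$kasp_individuals)))
  invisible(x)
}

#' Clone sets for every individual x locus of the reference cohort
#'
#' @param ref A [reference_cohort()] object.
#' @param n_clones Clones per individual x locus.
#' @param error_rate,chimera_rate Clone noise parameters; the default error
#'   rate reflects high-fidelity polymerase cloning.
#' @param seed Integer seed.
#' @return List of `clone_set` objects.
#' @export
reference_clone_sets <- function(ref, n_clones = 12, error_rate = 2e-4,
                                 chimera_rate = 0.02, seed = 1) {
  out <- list()
  k <- 0L
  for (ind in ref$individuals) {
    for (lc in names(ref$loci)) {
      k <- k + 1L
      out[[k]] <- sample_clones(ind, lc, n_clones, error_rate, chimera_rate,
                                seed = child_seed(seed, k))
    }
  }
  out
}

#' qPCR plate for the reference cohort
#'
#' @param ref A [reference_cohort()] object.
#' @param seed Integer seed.
#' @param sdlog Lognormal copy-number noise.
#' @return Long plate data frame (sample, locus, target, replicate, copies).
#' @export
reference_qpcr_plate <- function(ref, seed = 1, sdlog = 0.1) {
  out <- list()
  for (k in seq_along(ref$individuals)) {
    out[[k]] <- simulate_qpcr(ref$individuals[[k]], ref$assay,
                              seed = child_seed(seed, 1000L + k),
                              sdlog = sdlog)
  }
  do.call(rbind, out)
}

#' KASP fluorescence records for the reference SNP-assay cohort
#'
#' @param ref A [reference_cohort()] object.
#' @param seed Integer seed.
#' @param noise_sd Gaussian fluorescence noise.
#' @return Data frame (sample, locus, x, y).
#' @export
reference_kasp <- function(ref, seed = 1, noise_sd = 0.03) {
  out <- list()
  for (k in seq_along(ref$kasp_individuals)) {
    out[[k]] <- simulate_kasp(ref$kasp_individuals[[k]], ref$panel,
                              seed = child_seed(seed, 2000L + k),
                              noise_sd = noise_sd)
  }
  do.call(rbind, out)
}

#' Figure-style allele alignment from planted truth
#'
#' Builds, for one locus, the synthetic counterpart of a published allele
#' alignment: each individual's true allele sequences labelled
#' `<individual>-<alleleID>` (host alleles numbered, cancer alleles keeping
#' their lineage letters).  This is the deterministic curated-allele view of
#' the cohort, against which parsing and Hamming-count checks run.
#'
#' @param ref A [reference_cohort()] object.
#' @param locus Locus name.
#' @return Named character vector of aligned sequences.
#' @export
reference_allele_alignment <- function(ref, locus) {
  out <- character(0)
  for (ind in ref$individuals) {
    tmpl <- ind$templates[[locus]]
    host <- tmpl[tmpl$origin == "host", , drop = FALSE]
    labs <- if (!is.null(ind$mito[[locus]])) {
      host$label  # female / male
    } else {
      as.character(seq_len(nrow(host)))
    }
    nm <- paste(ind$id, labs, sep = "-")
    add <- stats::setNames(host$sequence, nm)
    cancer <- tmpl[tmpl$origin == "cancer", , drop = FALSE]
    if (nrow(cancer) > 0) {
      add <- c(add, stats::setNames(cancer$sequence,
                                    paste(ind$id, cancer$label, sep = "-")))
    }
    out <- c(out, add)
  }
  out
}
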