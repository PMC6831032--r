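# Synthetic cohort generator.  Emulates the statistical structure the
# downstream analysis assumes: species-structured allele pools, diploid
# nuclear genotypes with occasional introgression, doubly-uniparental
# mitochondrial inheritance (DUI), a clonal polyploid cancer genotype
# superimposed on host genotypes, clone sampling with point errors and
# single-crossover chimeras, allele-specific qPCR copy counts, and bimodal
# KASP fluorescence.  Planted truth is carried on every object so parameter
# recovery can be tested.

#' Generate species-structured allele pools
#'
#' Allele sequences are generated on a star genealogy per species: a shared
#' ancestor is mutated into one ancestor per species (at a rate set by the
#' divergence matrix), and each allele is the species ancestor plus a
#' Poisson number of private substitutions.  Intra-species divergence is
#' therefore much smaller than inter-species divergence by construction.
#' Mitochondrial loci additionally carry a deeply diverged male reference
#' haplotype per species, modelling the DUI male lineage.
#'
#' @param n_species Number of species pools.
#' @param loci Named list of [locus_spec()] objects.
#' @param divergence Expected substitutions/site between species pools;
#'   scalar or a symmetric `n_species x n_species` matrix with zero diagonal.
#' @param n_alleles Alleles per locus per species.
#' @param intra_mutations Mean private substitutions per allele.
#' @param male_divergence Divergence of the male mitochondrial lineage from
#'   the female lineage (substitutions/site).
#' @param male_loci Names of mitochondrial loci that carry a modelled male
#'   lineage; `NULL` (default) models one for every mito locus.
#' @param min_allele_distance Minimum pairwise Hamming distance between
#'   alleles of one pool (keeps alleles distinguishable above the curation
#'   collapse thresholds).
#' @param freq_shape Dirichlet concentration of the allele frequencies
#'   (larger = more even).
#' @param species_names Optional character vector of species labels.
#' @param seed Integer seed; identical seeds reproduce identical pools.
#' @return List of `species_pool` objects.
#' @examples
#' pools <- make_species_pools(3, divergence = 0.05, seed = 1)
#' @export
make_species_pools <- function(n_species, loci = default_loci(),
                               divergence = 0.05, n_alleles = 6,
                               intra_mutations = 3, male_divergence = 0.15,
                               male_loci = NULL, min_allele_distance = 3,
                               freq_shape = 5, species_names = NULL,
                               seed = NULL) {
  for (l in loci) {
    if (l$length < 50) stop("locus ", l$name, " shorter than 50 sites; too short for divergence targets")
  }
  if (is.matrix(divergence)) {
    D <- divergence
    if (!isSymmetric(unname(D)) || any(diag(D) != 0)) {
      stop("divergence matrix must be symmetric with zero diagonal")
    }
  } else {
    D <- matrix(divergence, n_species, n_species)
    diag(D) <- 0
  }
  if (is.null(species_names)) species_names <- paste0("sp", seq_len(n_species))
  # Per-species branch length from the shared ancestor: least-squares star fit.
  r <- if (n_species > 1) rowSums(D) / (n_species - 1) / 2 else 0

  with_seed(seed, {
    pools <- vector("list", n_species)
    anc <- lapply(loci, function(l) random_seq(l$length))
    male_anc <- lapply(loci, function(l) {
      if (l$category == "mito") mutate_seq(anc[[l$name]], round(male_divergence * l$length)) else NULL
    })
    names(anc) <- names(male_anc) <- names(loci)
    star_alleles <- function(ancestor, n) {
      # star genealogy: each allele = ancestor + private Poisson mutations,
      # kept at least min_allele_distance apart so alleles are
      # distinguishable above the curation collapse thresholds
      alleles <- character(0)
      for (k in seq_len(n)) {
        for (try in 1:40) {
          cand <- mutate_seq(ancestor,
                             max(rpois(1, intra_mutations) + (try - 1L),
                                 min_allele_distance))
          if (length(alleles) == 0 ||
              min(hamming_to_all(cand, alleles)) >= min_allele_distance) break
        }
        alleles <- c(alleles, cand)
      }
      alleles
    }
    # expected private mutations per allele (the star tips), used to debit
    # the species-branch length so realized inter-pool divergence matches
    # the requested rate
    kk <- 0:60
    m_bar <- sum(pmax(kk, min_allele_distance) * stats::dpois(kk, intra_mutations))
    for (i in seq_len(n_species)) {
      pool_loci <- list()
      for (l in loci) {
        sp_anc <- mutate_seq(anc[[l$name]],
                             rpois(1, max(0, r[i] * l$length - m_bar)))
        alleles <- star_alleles(sp_anc, n_alleles)
        freqs <- rgamma(n_alleles, shape = freq_shape)
        freqs <- freqs / sum(freqs)
        male_ref <- NULL
        male_alleles <- NULL
        male_freqs <- NULL
        if (l$category == "mito" &&
            (is.null(male_loci) || l$name %in% male_loci)) {
          male_ref <- mutate_seq(male_anc[[l$name]], rpois(1, r[i] * l$length))
          male_alleles <- star_alleles(male_ref, max(3L, n_alleles %/% 2L))
          male_freqs <- rgamma(length(male_alleles), shape = freq_shape)
          male_freqs <- male_freqs / sum(male_freqs)
        }
        pool_loci[[l$name]] <- list(alleles = alleles, freqs = freqs,
                                    male_ref = male_ref,
                                    male_alleles = male_alleles,
                                    male_freqs = male_freqs)
      }
      pools[[i]] <- structure(
        list(species = species_names[i], loci = pool_loci,
             locus_specs = loci),
        class = "species_pool"
      )
    }
    names(pools) <- species_names
    pools
  })
}

#' @export
print.species_pool <- function(x, ...) {
  cat(sprintf("<species pool %s: %d loci, %d alleles each>\n",
              x$species, length(x$loci), length(x$loci[[1]]$alleles)))
  invisible(x)
}

# Mean pairwise Hamming divergence (sites) between two pools at a locus.
pool_divergence <- function(pool_a, pool_b, locus) {
  a <- pool_a$loci[[locus]]$alleles
  b <- pool_b$loci[[locus]]$alleles
  mean(outer(seq_along(a), seq_along(b),
             Vectorize(function(i, j) hamming_distance(a[i], b[j]))))
}

#' Construct a clonal cancer lineage genotype
#'
#' Draws a polyploid founder genotype from one species pool: two distinct
#' founder alleles per nuclear locus, each present in `ploidy/2` copies.
#' With `hprime = TRUE` one copy of the second allele carries a single de
#' novo substitution (a near-duplicate pair in the style of a true second
#' copy arising after genome duplication).  Mitochondrial control-region
#' alleles are female/male single-crossover recombinants at two distinct
#' crossover points (a major allele and a minor heteroplasmic allele); the
#' major allele may sit inside a control-region tandem repeat
#' (`repeat_copies` copies per genome).  Other mito loci get one
#' non-recombinant female-type allele.
#'
#' @param pools Output of [make_species_pools()].
#' @param source_species Species the lineage arose in.
#' @param ploidy Nuclear copies per locus (>= 2, even).
#' @param hprime Add a one-substitution near-duplicate of the second nuclear
#'   allele at the first nuclear locus.
#' @param recombinant_mito Make mtCR-style alleles female/male recombinants.
#' @param mito_c_fraction Template fraction of the minor heteroplasmic
#'   control-region allele within cancer mitochondria.
#' @param repeat_copies Tandem-repeat copy number of the major control-region
#'   allele (1 = no repeat).
#' @param labels Optional named list, per locus, of allele labels.
#' @param seed Integer seed.
#' @return A `cancer_lineage` object with planted truth (crossover points).
#' @export
make_cancer_lineage <- function(pools, source_species = names(pools)[1],
                                ploidy = 4, hprime = FALSE,
                                recombinant_mito = TRUE,
                                mito_c_fraction = 0.005, repeat_copies = 3,
                                labels = NULL, seed = NULL) {
  stopifnot(ploidy >= 2, ploidy %% 2 == 0)
  pool <- pools[[source_species]]
  loci <- pool$locus_specs
  with_seed(seed, {
    nuclear <- list()
    first_nuc <- TRUE
    for (l in nuclear_loci(loci)) {
      pl <- pool$loci[[l$name]]
      founders <- sample(pl$alleles, 2, replace = FALSE, prob = pl$freqs)
      lab <- labels[[l$name]] %||% paste0(l$name, "-c", 1:2)
      df <- data.frame(sequence = founders, copies = ploidy / 2,
                       label = lab[1:2], stringsAsFactors = FALSE)
      if (hprime && first_nuc) {
        # one copy of the second allele acquires a single substitution
        df$copies[2] <- ploidy / 2 - 1
        df <- rbind(df, data.frame(
          sequence = mutate_seq(founders[2], 1), copies = 1,
          label = if (length(lab) >= 3) lab[3] else paste0(lab[2], "'"),
          stringsAsFactors = FALSE))
      }
      nuclear[[l$name]] <- df
      first_nuc <- FALSE
    }
    mito <- list()
    parents <- list()
    crossovers <- list()
    first_mito <- TRUE
    for (l in mito_loci(loci)) {
      pl <- pool$loci[[l$name]]
      f <- sample(pl$alleles, 1, prob = pl$freqs)
      lab <- labels[[l$name]] %||% paste0(l$name, "-m", 1:2)
      if (recombinant_mito && !is.null(pl$male_alleles) && first_mito) {
        m <- sample(pl$male_alleles, 1, prob = pl$male_freqs)
        inf <- which(strsplit(f, "")[[1]] != strsplit(m, "")[[1]])
        if (length(inf) < 6) stop("too few informative female/male sites for recombinants")
        # crossovers fall between informative sites near 75% (major, switches
        # to male-like toward the 3' end) and 40% (minor) of the sequence
        k_major <- inf[ceiling(length(inf) * 0.75)]
        k_minor <- inf[ceiling(length(inf) * 0.40)]
        mito[[l$name]] <- data.frame(
          sequence = c(splice_seqs(f, m, k_minor), splice_seqs(f, m, k_major)),
          fraction = c(mito_c_fraction, 1 - mito_c_fraction),
          label = lab[1:2],
          repeat_copies = c(1, repeat_copies),
          crossover = c(k_minor, k_major),
          stringsAsFactors = FALSE)
        parents[[l$name]] <- list(female = f, male = m)
        crossovers[[l$name]] <- c(k_minor, k_major)
        first_mito <- FALSE
      } else {
        mito[[l$name]] <- data.frame(
          sequence = mutate_seq(f, 2), fraction = 1, label = lab[1],
          repeat_copies = 1, crossover = NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
    structure(
      list(source_species = source_species, ploidy = ploidy,
           nuclear = nuclear, mito = mito, mito_parents = parents,
           truth = list(crossovers = crossovers)),
      class = "cancer_lineage"
    )
  })
}

#' @export
print.cancer_lineage <- function(x, ...) {
  cat(sprintf("<cancer lineage from %s; ploidy %d>\n", x$source_species, x$ploidy))
  for (nm in names(x$nuclear)) {
    cat(" ", nm, ":", paste(x$nuclear[[nm]]$label, collapse = ", "), "\n")
  }
  for (nm in names(x$mito)) {
    cat(" ", nm, ":", paste(x$mito[[nm]]$label, collapse = ", "), "\n")
  }
  invisible(x)
}

# Resolve the template pool (sequence, fraction, origin, label, repeat copies)
# for one individual at one locus.  cancer_burden maps linearly to template
# fraction; each polyploid cancer allele contributes burden * copies/ploidy.
resolve_templates <- function(nuclear, mito, species, burden, lineage,
                              loci) {
  templates <- list()
  for (l in loci) {
    if (l$category == "nuclear") {
      host <- data.frame(sequence = nuclear[[l$name]],
                         fraction = (1 - burden) / 2,
                         origin = "host",
                         label = paste0("h", seq_along(nuclear[[l$name]])),
                         repeat_copies = 1, stringsAsFactors = FALSE)
    } else {
      mt <- mito[[l$name]]
      seqs <- mt$female
      labs <- "female"
      w <- 1
      if (!is.null(mt$male)) {
        seqs <- c(seqs, mt$male)
        labs <- c(labs, "male")
        w <- c(0.7, 0.3)  # male mitogenome is a minor template in somatic DNA
      }
      host <- data.frame(sequence = seqs, fraction = (1 - burden) * w,
                         origin = "host", label = labs, repeat_copies = 1,
                         stringsAsFactors = FALSE)
    }
    if (burden > 0 && !is.null(lineage)) {
      if (l$category == "nuclear") {
        la <- lineage$nuclear[[l$name]]
        cancer <- data.frame(sequence = la$sequence,
                             fraction = burden * la$copies / lineage$ploidy,
                             origin = "cancer", label = la$label,
                             repeat_copies = 1, stringsAsFactors = FALSE)
      } else {
        la <- lineage$mito[[l$name]]
        cancer <- data.frame(sequence = la$sequence,
                             fraction = burden * la$fraction,
                             origin = "cancer", label = la$label,
                             repeat_copies = la$repeat_copies,
                             stringsAsFactors = FALSE)
      }
      host <- rbind(host, cancer)
    }
    # merge identical sequences (e.g. homozygotes)
    agg <- stats::aggregate(fraction ~ sequence, data = host, FUN = sum)
    first <- host[!duplicated(host$sequence), c("sequence", "origin", "label", "repeat_copies")]
    out <- merge(first, agg, by = "sequence", sort = FALSE)
    out$fraction <- out$fraction / sum(out$fraction)
    templates[[l$name]] <- out
  }
  templates
}

# Build one simulated individual (uses the current RNG stream).
make_individual <- function(pools, species, id, site = "site1",
                            diagnosis = "normal", burden = 0,
                            lineage = NULL, hybrid_donor = NULL,
                            p_male = 0.5, distinct_host_alleles = FALSE,
                            introgressed_snp_loci = integer(0),
                            n_snp_loci = 13) {
  pool <- pools[[species]]
  loci <- pool$locus_specs
  nuclear <- list()
  for (l in nuclear_loci(loci)) {
    pl <- pool$loci[[l$name]]
    g <- sample(pl$alleles, 2, replace = !distinct_host_alleles, prob = pl$freqs)
    if (!is.null(hybrid_donor)) {
      dp <- pools[[hybrid_donor]]$loci[[l$name]]
      g[2] <- sample(dp$alleles, 1, prob = dp$freqs)
    }
    nuclear[[l$name]] <- g
  }
  has_male <- stats::runif(1) < p_male
  mito <- list()
  for (l in mito_loci(loci)) {
    pl <- pool$loci[[l$name]]
    female <- sample(pl$alleles, 1, prob = pl$freqs)
    male <- NULL
    if (has_male && !is.null(pl$male_alleles)) {
      male <- sample(pl$male_alleles, 1, prob = pl$male_freqs)
    }
    mito[[l$name]] <- list(female = female, male = male)
  }
  if (diagnosis == "normal") burden <- 0
  structure(
    list(id = id, species = species, site = site, diagnosis = diagnosis,
         is_hybrid = !is.null(hybrid_donor), cancer_burden = burden,
         nuclear = nuclear, mito = mito,
         introgressed_snp_loci = introgressed_snp_loci,
         templates = resolve_templates(nuclear, mito, species, burden,
                                       lineage, loci)),
    class = "sim_individual"
  )
}

#' @export
print.sim_individual <- function(x, ...) {
  cat(sprintf("<individual %s: %s, %s, %s%s>\n", x$id, x$species, x$site,
              x$diagnosis,
              if (x$cancer_burden > 0) sprintf(" (burden %.2f)", x$cancer_burden) else ""))
  invisible(x)
}

#' Simulate a cohort of individuals
#'
#' Draws `n` individuals from one species pool: diploid nuclear genotypes by
#' pool allele frequency, one female mitochondrial allele always and a male
#' allele with probability `p_male` (DUI).  With probability `prevalence`
#' an individual is diseased and carries the cancer lineage's alleles on top
#' of its own, at a template fraction (`cancer_burden`) drawn uniformly from
#' `burden_range`.  With probability `hybrid_rate` an individual carries one
#' allospecific nuclear allele per locus from a random other species.
#'
#' @param pools Output of [make_species_pools()].
#' @param n Individuals to simulate.
#' @param species Species name (recycled over individuals).
#' @param site Site label (recycled).
#' @param prevalence Disease prevalence in `[0, 1]`.
#' @param lineage A [make_cancer_lineage()] object (required if
#'   `prevalence > 0`).
#' @param hybrid_rate Fraction of individuals carrying allospecific alleles.
#' @param p_male Probability of carrying the male mitochondrial lineage.
#' @param burden_range Range of the cancer template fraction for diseased
#'   individuals.
#' @param introgression_rate Fraction of individuals introgressed at one
#'   diagnostic SNP locus (a tenth of these at two loci).
#' @param distinct_host_alleles Force heterozygous nuclear genotypes.
#' @param ids Optional individual IDs.
#' @param seed Integer seed.
#' @return A `sim_cohort` object (list of individuals plus planted truth).
#' @export
make_cohort <- function(pools, n = 60, species = names(pools)[1],
                        site = "site1", prevalence = 0.1, lineage = NULL,
                        hybrid_rate = 0, p_male = 0.5,
                        burden_range = c(0.4, 0.7),
                        introgression_rate = 0,
                        distinct_host_alleles = FALSE, ids = NULL,
                        seed = NULL) {
  if (length(pools) == 0) stop("empty pool list")
  stopifnot(prevalence >= 0, prevalence <= 1)
  if (prevalence > 0 && is.null(lineage)) stop("prevalence > 0 requires a lineage")
  species <- rep_len(species, n)
  site <- rep_len(site, n)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  with_seed(seed, {
    inds <- vector("list", n)
    for (i in seq_len(n)) {
      diseased <- stats::runif(1) < prevalence
      donor <- NULL
      if (stats::runif(1) < hybrid_rate && length(pools) > 1) {
        donor <- sample(setdiff(names(pools), species[i]), 1)
      }
      intro <- integer(0)
      if (stats::runif(1) < introgression_rate) {
        k <- if (stats::runif(1) < 0.1) 2L else 1L
        intro <- sample.int(13L, k)
      }
      inds[[i]] <- make_individual(
        pools, species[i], ids[i], site[i],
        diagnosis = if (diseased) "cancer" else "normal",
        burden = if (diseased) stats::runif(1, burden_range[1], burden_range[2]) else 0,
        lineage = lineage, hybrid_donor = donor, p_male = p_male,
        distinct_host_alleles = distinct_host_alleles,
        introgressed_snp_loci = intro)
    }
    names(inds) <- ids
    structure(
      list(individuals = inds, pools = pools, lineage = lineage),
      class = "sim_cohort"
    )
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  d <- vapply(x$individuals, function(i) i$diagnosis, character(1))
  cat(sprintf("<simulated cohort: %d individuals (%d diseased), species: %s>\n",
              length(x$individuals), sum(d == "cancer"),
              paste(unique(vapply(x$individuals, function(i) i$species, character(1))),
                    collapse = ", ")))
  invisible(x)
}

#' Sample cloned sequences from one individual at one locus
#'
#' Each clone derives from one template allele (chosen proportionally to
#' template fractions, with cancer alleles weighted by the individual's
#' cancer burden) and carries a Poisson number of substitution errors
#' (`error_rate` per site).  With probability `chimera_rate` a clone is a
#' single-crossover PCR splice of two templates at a uniform crossover point.
#'
#' @param individual A `sim_individual`.
#' @param locus Locus name.
#' @param n_clones Clones picked (>= 1).
#' @param error_rate Substitutions/site per clone.
#' @param chimera_rate Probability a clone is a PCR chimera.
#' @param seed Integer seed.
#' @return A `clone_set`: individual id, locus, clone sequences (named
#'   `<id>_<locus>_c<k>`) and per-clone planted truth.
#' @export
sample_clones <- function(individual, locus, n_clones = 8,
                          error_rate = 0.001, chimera_rate = 0.02,
                          seed = NULL) {
  stopifnot(n_clones >= 1)
  tmpl <- individual$templates[[locus]]
  if (is.null(tmpl)) stop("locus ", locus, " not present in individual ", individual$id)
  L <- nchar(tmpl$sequence[1])
  with_seed(seed, {
    idx <- sample.int(nrow(tmpl), n_clones, replace = TRUE, prob = tmpl$fraction)
    clones <- character(n_clones)
    truth <- data.frame(template = tmpl$label[idx],
                        origin = tmpl$origin[idx],
                        chimera = FALSE, partner = NA_character_,
                        crossover = NA_integer_, n_errors = 0L,
                        stringsAsFactors = FALSE)
    for (k in seq_len(n_clones)) {
      s <- tmpl$sequence[idx[k]]
      if (nrow(tmpl) > 1 && stats::runif(1) < chimera_rate) {
        others <- setdiff(seq_len(nrow(tmpl)), idx[k])
        j <- others[sample.int(length(others), 1,
                               prob = tmpl$fraction[others])]
        cx <- sample.int(L - 1L, 1)
        s <- splice_seqs(s, tmpl$sequence[j], cx)
        truth$chimera[k] <- TRUE
        truth$partner[k] <- tmpl$label[j]
        truth$crossover[k] <- cx
      }
      ne <- stats::rpois(1, error_rate * L)
      truth$n_errors[k] <- ne
      clones[k] <- mutate_seq(s, ne)
    }
    names(clones) <- sprintf("%s_%s_c%d", individual$id, locus, seq_len(n_clones))
    structure(
      list(individual_id = individual$id, locus = locus, clones = clones,
           truth = truth),
      class = "clone_set"
    )
  })
}

#' @export
print.clone_set <- function(x, ...) {
  cat(sprintf("<clone set %s x %s: %d clones>\n", x$individual_id, x$locus,
              length(x$clones)))
  invisible(x)
}

#' Default allele-specific qPCR assay for a lineage
#'
#' One allele-specific target per cancer-associated allele plus a universal
#' target per locus.  By default the first nuclear locus is assayed with a
#' single allele-specific primer pair (targeting the second founder allele,
#' which also amplifies its one-substitution near-duplicate), and every
#' other locus with one pair per lineage allele.
#'
#' @param lineage A `cancer_lineage`.
#' @return Data frame (locus, allele label, target sequence, repeat copies).
#' @export
default_qpcr_assay <- function(lineage) {
  rows <- list()
  first <- TRUE
  for (nm in names(lineage$nuclear)) {
    la <- lineage$nuclear[[nm]]
    pick <- if (first) 2L else seq_len(min(nrow(la), 2L))
    rows[[length(rows) + 1]] <- data.frame(
      locus = nm, allele = la$label[pick], sequence = la$sequence[pick],
      repeat_copies = 1, stringsAsFactors = FALSE)
    first <- FALSE
  }
  for (nm in names(lineage$mito)) {
    la <- lineage$mito[[nm]]
    rows[[length(rows) + 1]] <- data.frame(
      locus = nm, allele = la$label, sequence = la$sequence,
      repeat_copies = la$repeat_copies, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate an allele-specific qPCR plate for one individual
#'
#' Universal primers amplify one conserved site per template genome; an
#' allele-specific primer pair amplifies templates within one substitution of
#' its target, multiplied by the target's tandem-repeat copy number.  Copy
#' numbers are reported per reaction in triplicate with lognormal noise.
#'
#' @param individual A `sim_individual`.
#' @param assay Assay table from [default_qpcr_assay()].
#' @param seed Integer seed.
#' @param sdlog Lognormal noise (0 = noise-free).
#' @param universal_nuclear,universal_mito Expected universal copies/reaction.
#' @param n_rep Replicates per reaction.
#' @return Long data frame: sample, locus, target, replicate, copies.
#' @export
simulate_qpcr <- function(individual, assay, seed = NULL, sdlog = 0.1,
                          universal_nuclear = 2e4, universal_mito = 1e5,
                          n_rep = 3) {
  loci <- unique(assay$locus)
  with_seed(seed, {
    out <- list()
    for (lc in loci) {
      tmpl <- individual$templates[[lc]]
      if (is.null(tmpl)) next
      is_mito <- !is.null(individual$mito[[lc]])
      u0 <- if (is_mito) universal_mito else universal_nuclear
      noisy <- function(mu) {
        if (mu <= 0) return(rep(0, n_rep))
        if (sdlog == 0) rep(mu, n_rep) else stats::rlnorm(n_rep, log(mu), sdlog)
      }
      out[[length(out) + 1]] <- data.frame(
        sample = individual$id, locus = lc, target = "universal",
        replicate = seq_len(n_rep), copies = noisy(u0),
        stringsAsFactors = FALSE)
      for (r in which(assay$locus == lc)) {
        hits <- hamming_to_all(assay$sequence[r], tmpl$sequence) <= 1
        # allele-specific amplification scales with the template fraction and
        # the tandem-repeat copy number of the matching templates
        match_frac <- sum(tmpl$fraction[hits] * tmpl$repeat_copies[hits])
        out[[length(out) + 1]] <- data.frame(
          sample = individual$id, locus = lc,
          target = assay$allele[r], replicate = seq_len(n_rep),
          copies = noisy(u0 * match_frac),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

#' Diagnostic SNP panel definition
#'
#' @param n Number of diagnostic loci (13 per host species in the standard
#'   design).
#' @param prefix Locus ID prefix.
#' @return Data frame with a `locus_id` column.
#' @export
make_snp_panel <- function(n = 13, prefix = "SNP") {
  data.frame(locus_id = sprintf("%s%02d", prefix, seq_len(n)),
             stringsAsFactors = FALSE)
}

#' Simulate KASP fluorescence for one individual
#'
#' At each diagnostic locus the fluorescence of the cancer-source-species
#' (M. trossulus) allele, `y`, is proportional to the trossulus template
#' fraction, and the host-allele fluorescence `x` to its complement, each
#' plus Gaussian noise (clamped at zero).  The trossulus template fraction is
#' the cancer burden (cancer cells are homozygous trossulus at diagnostic
#' loci) plus half the host fraction at introgressed heterozygous loci.
#'
#' @param individual A `sim_individual`.
#' @param panel Panel from [make_snp_panel()].
#' @param seed Integer seed.
#' @param noise_sd Gaussian fluorescence noise (0 = noise-free).
#' @return Data frame: sample, locus, x, y.
#' @export
simulate_kasp <- function(individual, panel, seed = NULL, noise_sd = 0.03) {
  b <- individual$cancer_burden
  host_t <- if (identical(individual$species, "M. trossulus")) {
    rep(1, nrow(panel))
  } else {
    ifelse(seq_len(nrow(panel)) %in% individual$introgressed_snp_loci, 0.5, 0)
  }
  t_frac <- b + (1 - b) * host_t
  with_seed(seed, {
    y <- pmax(0, t_frac + stats::rnorm(nrow(panel), 0, noise_sd))
    x <- pmax(0, (1 - t_frac) + stats::rnorm(nrow(panel), 0, noise_sd))
    data.frame(sample = individual$id, locus = panel$locus_id,
               x = x, y = y, stringsAsFactors = FALSE)
  })
}

#' Sample sheet for a simulated cohort
#'
#' @param cohort A `sim_cohort`.
#' @return Data frame: id, species, site, diagnosis.
#' @export
cohort_sample_sheet <- function(cohort) {
  do.call(rbind, lapply(cohort$individuals, function(i) {
    data.frame(id = i$id, species = i$species, site = i$site,
               diagnosis = i$diagnosis, stringsAsFactors = FALSE)
  })) -> df
  rownames(df) <- NULL
  df
}

#' Planted truth of a simulated cohort as a list (exportable as JSON)
#'
#' @param cohort A `sim_cohort`.
#' @return List with per-individual burdens and genotypes, plus the lineage
#'   allele sequences and mitochondrial crossovers when a lineage is present.
#' @export
cohort_truth <- function(cohort) {
  lin <- cohort$lineage
  list(
    individuals = lapply(cohort$individuals, function(i) {
      list(id = i$id, species = i$species, diagnosis = i$diagnosis,
           cancer_burden = i$cancer_burden, is_hybrid = i$is_hybrid,
           nuclear = i$nuclear,
           mito = lapply(i$mito, function(m) m[!vapply(m, is.null, logical(1))]),
           introgressed_snp_loci = i$introgressed_snp_loci)
    }),
    lineage = if (is.null(lin)) NULL else list(
      source_species = lin$source_species, ploidy = lin$ploidy,
      nuclear = lin$nuclear, mito = lin$mito,
      crossovers = lin$truth$crossovers)
  )
}

#' Write cohort data files (FASTA clones, sample sheet, truth JSON)
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @param clone_sets Optional list of `clone_set` objects to write as FASTA.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, clone_sets = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort_sample_sheet(cohort),
                     file.path(dir, "sample_sheet.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort_truth(cohort), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (cs in clone_sets) {
    write_fasta(cs$clones,
                file.path(dir, sprintf("clones_%s_%s.fasta",
                                       cs$individual_id, cs$locus)))
  }
  invisible(dir)
}
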