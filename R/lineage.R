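# Detection of transmissible-cancer signatures across a genotyped cohort:
# supernumerary alleles within individuals, cancer-associated alleles shared
# across diseased individuals and absent from normals, and lineage identity
# comparisons between cohorts.

#' Assemble a per-individual multi-locus genotype
#'
#' @param individual_id,species,site Identifiers from the sample sheet.
#' @param diagnosis `"normal"` or `"cancer"` — always taken from the sample
#'   sheet (histology), never inferred here.
#' @param calls Named list (by locus) of `allele_calls` data frames.
#' @return An `individual_genotype` object.
#' @export
individual_genotype <- function(individual_id, species, site = NA,
                                diagnosis = c("normal", "cancer"), calls) {
  diagnosis <- match.arg(diagnosis)
  structure(list(individual_id = individual_id, species = species,
                 site = site, diagnosis = diagnosis, calls = calls),
            class = "individual_genotype")
}

#' @export
print.individual_genotype <- function(x, ...) {
  cat(sprintf("<genotype %s (%s, %s): %s>\n", x$individual_id, x$species,
              x$diagnosis,
              paste(sprintf("%s:%d", names(x$calls),
                            vapply(x$calls, nrow, integer(1))),
                    collapse = " ")))
  invisible(x)
}

#' Count distinct curated alleles at one locus
#'
#' For nuclear loci a count above two sets the supernumerary flag — the
#' signature of a host genotype plus a superimposed cancer genotype, since a
#' diploid individual carries at most two alleles.  Mitochondrial loci are
#' exempt: under doubly-uniparental inheritance an individual may carry a
#' female and a male haplotype, so only counts above the DUI expectation
#' would be anomalous and they are not flagged here.
#'
#' @param g An `individual_genotype`.
#' @param locus Locus name.
#' @param category `"nuclear"` or `"mito"`.
#' @return Integer count with attribute `supernumerary`.
#' @export
count_alleles <- function(g, locus, category = "nuclear") {
  if (!locus %in% names(g$calls)) {
    stop("locus ", locus, " missing from genotype of ", g$individual_id)
  }
  n <- length(unique(g$calls[[locus]]$sequence))
  structure(n, supernumerary = (category == "nuclear" && n > 2))
}

# All allele sequences of one individual at one locus.
alleles_of <- function(g, locus) unique(g$calls[[locus]]$sequence)

# Is `seq` within `radius` differences of any sequence in `set`?
near_any <- function(seq, set, radius) {
  length(set) > 0 && any(hamming_to_all(seq, set) <= radius)
}

#' Find cancer-associated alleles shared across diseased individuals
#'
#' An allele is cancer-associated when it is present (within
#' `near_match_radius` differences, accommodating de novo mutations of the
#' clonal lineage) in at least two diseased individuals and absent (within
#' the same radius) from every normal individual.  Each diseased
#' individual's remaining alleles are its host alleles.
#'
#' Two guards keep identical-by-state host alleles out of the profile.
#' First, candidate alleles must carry multi-clone support in at least one
#' diseased individual (extending the curation rule that a presented allele
#' is found in at least two clones), or be called identically in at least
#' two diseased individuals — two independent identical calls cannot
#' plausibly be the same random PCR error.  Second, the sharing requirement
#' counts only diseased individuals whose genotype at the locus is
#' *anomalous*: more distinct calls than a normal individual could carry
#' (above `expected_alleles` of the [locus_spec()]: 2 for a diploid nuclear
#' locus; for mito loci the doubly-uniparental expectation of a female plus
#' optionally a male haplotype).  An allele shared only among
#' normal-looking diseased genotypes is indistinguishable from host-allele
#' identity by state and is not called cancer-associated.
#'
#' @param genotypes List of `individual_genotype` objects (with diagnoses).
#' @param locus Locus name, or a [locus_spec()] (which supplies
#'   `expected_alleles`).
#' @param near_match_radius Maximum differences for a near match (default 1).
#' @param expected_alleles Normal per-individual allele count at this locus
#'   (used when `locus` is a bare name; default 2).
#' @return A `lineage_profile` fragment: data frame with `locus`,
#'   `sequence`, `label`, `n_diseased` (all diseased carriers),
#'   `n_anomalous` (carriers with anomalous genotypes) and a list-column
#'   `supporting` of individual IDs.
#' @export
find_shared_cancer_alleles <- function(genotypes, locus,
                                       near_match_radius = 1,
                                       expected_alleles = 2L) {
  if (inherits(locus, "locus_spec")) {
    expected_alleles <- locus$expected_alleles
    locus <- locus$name
  }
  diag <- vapply(genotypes, function(g) g$diagnosis, character(1))
  diseased <- genotypes[diag == "cancer"]
  normals <- genotypes[diag == "normal"]
  if (length(diseased) < 1) {
    return(empty_profile(locus))
  }
  normal_alleles <- unlist(lapply(normals, alleles_of, locus = locus),
                           use.names = FALSE)
  multi <- unique(unlist(lapply(diseased, function(g) {
    calls <- g$calls[[locus]]
    if (is.null(calls)) return(NULL)
    calls$sequence[calls$support >= 2]
  }), use.names = FALSE))
  anom <- vapply(diseased, function(g) {
    length(alleles_of(g, locus)) > expected_alleles
  }, logical(1))
  counts <- table(unlist(lapply(diseased[anom], alleles_of, locus = locus),
                         use.names = FALSE))
  shared_exact <- names(counts)[counts >= 2]
  cand <- union(multi, shared_exact)
  rows <- list()
  for (s in cand) {
    carriers <- vapply(diseased, function(g) {
      near_any(s, alleles_of(g, locus), near_match_radius)
    }, logical(1))
    in_normal <- near_any(s, normal_alleles, near_match_radius)
    if (sum(carriers & anom) >= 2 && !in_normal) {
      rows[[length(rows) + 1]] <- data.frame(
        locus = locus, sequence = s,
        n_diseased = sum(carriers), n_anomalous = sum(carriers & anom),
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$supporting <- list(
        vapply(diseased[carriers], function(g) g$individual_id, character(1)))
    }
  }
  if (length(rows) == 0) return(empty_profile(locus))
  out <- do.call(rbind, rows)
  # deduplicate near-identical representatives: keep each sequence once
  out <- out[!duplicated(out$sequence), , drop = FALSE]
  out <- out[order(-out$n_diseased, out$sequence), , drop = FALSE]
  out$label <- LETTERS[seq_len(nrow(out))]
  rownames(out) <- NULL
  class(out) <- c("lineage_profile", "data.frame")
  out
}

empty_profile <- function(locus = character(0)) {
  out <- data.frame(locus = character(0), sequence = character(0),
                    n_diseased = integer(0), n_anomalous = integer(0),
                    stringsAsFactors = FALSE)
  out$supporting <- list()
  out$label <- character(0)
  class(out) <- c("lineage_profile", "data.frame")
  out
}

#' Combine per-locus profile fragments into one lineage profile
#'
#' @param ... `lineage_profile` fragments (or a single list of them).
#' @param label_map Optional named character vector `sequence -> label` to
#'   reproduce published allele letters.
#' @return A `lineage_profile` data frame covering all loci.
#' @export
lineage_profile <- function(..., label_map = NULL) {
  frags <- list(...)
  if (length(frags) == 1 && !inherits(frags[[1]], "data.frame")) frags <- frags[[1]]
  out <- do.call(rbind, frags)
  if (!is.null(label_map)) {
    hit <- out$sequence %in% names(label_map)
    out$label[hit] <- unname(label_map[out$sequence[hit]])
  }
  rownames(out) <- NULL
  class(out) <- c("lineage_profile", "data.frame")
  out
}

#' @export
print.lineage_profile <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("<empty lineage profile>\n")
    return(invisible(x))
  }
  cat("Cancer lineage profile:\n")
  for (lc in unique(x$locus)) {
    sub <- x[x$locus == lc, ]
    cat(sprintf("  %s: %s\n", lc,
                paste(sprintf("%s (%d diseased)", sub$label, sub$n_diseased),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Group near-duplicate profile alleles into polyploid families
#'
#' Profile alleles at the same locus within `radius` differences of each
#' other (transitively) are grouped as one family — e.g. an allele and its
#' single-substitution second copy arising after genome duplication.  Both
#' sequences are retained.
#'
#' @param profile A `lineage_profile`.
#' @param radius Maximum differences within a family (>= 1; 0 disables
#'   merging).
#' @return `profile` with an added `family` column (per-locus family index).
#' @export
merge_near_duplicates <- function(profile, radius = 1) {
  if (nrow(profile) == 0) {
    profile$family <- integer(0)
    return(profile)
  }
  profile$family <- NA_integer_
  for (lc in unique(profile$locus)) {
    idx <- which(profile$locus == lc)
    n <- length(idx)
    if (n == 0) next
    if (radius < 1) {
      profile$family[idx] <- seq_len(n)
      next
    }
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        adj[i, j] <- i == j ||
          hamming_distance(profile$sequence[idx[i]], profile$sequence[idx[j]]) <= radius
      }
    }
    # connected components by repeated expansion
    comp <- rep(NA_integer_, n)
    k <- 0L
    for (i in seq_len(n)) {
      if (!is.na(comp[i])) next
      k <- k + 1L
      front <- i
      while (length(front) > 0) {
        comp[front] <- k
        front <- which(is.na(comp) & apply(adj[, front, drop = FALSE], 1, any))
      }
    }
    profile$family[idx] <- comp
  }
  profile
}

#' Compare two lineage profiles locus by locus
#'
#' Each shared locus gets a verdict: `identical` (equal sequence sets),
#' `near-identical` (each allele within `radius` of one on the other side,
#' differences listed), or `distinct`.  The overall same-lineage call
#' requires all shared nuclear loci identical or near-identical;
#' mitochondrial discordance is reported but does not veto, because a
#' transmissible lineage can lose heteroplasmy or capture a host
#' mitochondrial genome.
#'
#' @param profile_a,profile_b `lineage_profile` objects.
#' @param loci Named list of [locus_spec()] (to tell nuclear from mito loci).
#' @param radius Near-match radius (default 1).
#' @return A `lineage_comparison`: per-locus data frame plus
#'   `same_lineage` attribute.
#' @export
compare_lineages <- function(profile_a, profile_b, loci = default_loci(),
                             radius = 1) {
  shared <- intersect(unique(profile_a$locus), unique(profile_b$locus))
  if (length(shared) == 0) stop("profiles share no locus")
  rows <- list()
  for (lc in shared) {
    a <- profile_a$sequence[profile_a$locus == lc]
    b <- profile_b$sequence[profile_b$locus == lc]
    if (setequal(a, b) && length(a) > 0) {
      verdict <- "identical"; ndiff <- 0L
    } else {
      a_near <- vapply(a, function(s) near_any(s, b, radius), logical(1))
      b_near <- vapply(b, function(s) near_any(s, a, radius), logical(1))
      if (length(a) > 0 && length(b) > 0 && all(a_near) && all(b_near)) {
        verdict <- "near-identical"
        ndiff <- sum(!vapply(a, function(s) s %in% b, logical(1))) +
          sum(!vapply(b, function(s) s %in% a, logical(1)))
      } else {
        verdict <- "distinct"
        ndiff <- NA_integer_
      }
    }
    cat_lc <- if (lc %in% names(loci)) loci[[lc]]$category else "nuclear"
    rows[[length(rows) + 1]] <- data.frame(
      locus = lc, category = cat_lc, verdict = verdict,
      listed_differences = ndiff, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  nuc <- out[out$category == "nuclear", ]
  same <- nrow(nuc) > 0 && all(nuc$verdict %in% c("identical", "near-identical"))
  attr(out, "same_lineage") <- same
  attr(out, "mito_discordant") <- any(out$category == "mito" & out$verdict == "distinct")
  class(out) <- c("lineage_comparison", "data.frame")
  out
}

#' @export
print.lineage_comparison <- function(x, ...) {
  cat("Lineage comparison:\n")
  print(data.frame(x), row.names = FALSE)
  cat(sprintf("Same lineage: %s%s\n", attr(x, "same_lineage"),
              if (isTRUE(attr(x, "mito_discordant")))
                " (mitochondrial discordance reported, not vetoing)" else ""))
  invisible(x)
}

#' Classify genotyped individuals against a lineage profile
#'
#' @param genotypes List of `individual_genotype` objects.
#' @param profile A `lineage_profile`.
#' @param radius Near-match radius.
#' @param min_loci Minimum number of loci with profile alleles for a
#'   lineage-positive call (multi-locus concordance; 1 accepts single-locus
#'   evidence).
#' @return Data frame: id, diagnosis, lineage-positive loci count, and
#'   classification `normal` / `lineage-positive` / `non-lineage neoplasia`.
#'   Diseased individuals carrying none (or fewer than `min_loci`) of the
#'   profile alleles are non-lineage neoplasia, not errors.
#' @export
classify_individuals <- function(genotypes, profile, radius = 1,
                                 min_loci = 1) {
  do.call(rbind, lapply(genotypes, function(g) {
    hits <- 0L
    for (lc in intersect(unique(profile$locus), names(g$calls))) {
      prof <- profile$sequence[profile$locus == lc]
      if (any(vapply(alleles_of(g, lc), function(s) near_any(s, prof, radius),
                     logical(1)))) {
        hits <- hits + 1L
      }
    }
    cls <- if (g$diagnosis == "normal") {
      "normal"
    } else if (hits >= min_loci) {
      "lineage-positive"
    } else {
      "non-lineage neoplasia"
    }
    data.frame(id = g$individual_id, species = g$species,
               diagnosis = g$diagnosis, lineage_loci = hits,
               classification = cls, stringsAsFactors = FALSE)
  })) -> out
  rownames(out) <- NULL
  out
}

#' Presence/absence matrix of profile alleles across individuals
#'
#' @param genotypes List of `individual_genotype` objects.
#' @param profile A `lineage_profile`.
#' @param radius Near-match radius.
#' @return Logical matrix, individuals x (locus:allele).
#' @export
presence_matrix <- function(genotypes, profile, radius = 1) {
  cols <- sprintf("%s:%s", profile$locus, profile$label)
  m <- matrix(FALSE, length(genotypes), nrow(profile),
              dimnames = list(vapply(genotypes, function(g) g$individual_id,
                                     character(1)), cols))
  for (i in seq_along(genotypes)) {
    for (j in seq_len(nrow(profile))) {
      lc <- profile$locus[j]
      if (lc %in% names(genotypes[[i]]$calls)) {
        m[i, j] <- near_any(profile$sequence[j],
                            alleles_of(genotypes[[i]], lc), radius)
      }
    }
  }
  m
}
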