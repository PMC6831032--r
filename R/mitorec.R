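# Characterization of mitochondrial cancer alleles: female/male
# recombination breakpoints (maximum chi-square scan over informative
# sites), heteroplasmy bookkeeping, and control-region tandem repeats.
# Coordinates are 0-based half-open throughout; crossover intervals are
# reported between informative sites because a crossover cannot be resolved
# inside a tract where the parents are identical.

#' Parental reference pair for breakpoint scanning
#'
#' @param female,male Aligned female and male reference sequences (equal
#'   length).
#' @return A `parental_pair`; informative sites are the positions where the
#'   two references carry different unambiguous bases.
#' @export
parental_pair <- function(female, male) {
  if (nchar(female) != nchar(male)) stop("parental sequences have unequal lengths")
  rf <- charToRaw(toupper(female)); rm_ <- charToRaw(toupper(male))
  bases <- charToRaw(paste(DNA_BASES, collapse = ""))
  informative <- which(rf != rm_ & (rf %in% bases) & (rm_ %in% bases))
  structure(list(female = toupper(female), male = toupper(male),
                 informative = informative),
            class = "parental_pair")
}

# 2x2 chi-square statistic (no continuity correction); 0 when a margin is 0.
chisq2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  if (den == 0) return(0)
  n * (a * d - b * c)^2 / den
}

#' Scan a mitochondrial allele for a female/male recombination breakpoint
#'
#' At every informative site the query is scored as matching the female or
#' the male reference (sites matching neither — private mutations — are set
#' aside).  A maximum chi-square scan over all split points of the
#' informative-site match vector finds the best single crossover.  The
#' verdict is `single-crossover` when the best split is significant
#' (chi-square >= `chi_threshold`) and each side matches one parent at
#' >= `purity` of its informative sites; `non-recombinant` when the query
#' matches a single parent with at most one discordant informative site
#' (noise floor); `complex` otherwise; `uninformative` with fewer than 4
#' usable informative sites.
#'
#' The crossover interval is reported 0-based half-open, spanning from just
#' after the last informative site of the left segment up to and including
#' the first informative site of the right segment: the true crossover
#' position (the first 0-based position derived from the right-hand parent)
#' lies in `[interval_start, interval_end)`.
#'
#' @param query Aligned query sequence.
#' @param parents A [parental_pair()].
#' @param chi_threshold Minimum chi-square for a crossover call (3.84 = 5%
#'   point of chi-square with 1 df).
#' @param purity Minimum fraction of informative sites on each side matching
#'   its parent.
#' @return A `breakpoint_call`: verdict, per-segment parental assignment,
#'   interval, chi-square, informative-site bookkeeping.
#' @export
find_breakpoint <- function(query, parents, chi_threshold = 3.84,
                            purity = 0.9) {
  stopifnot(inherits(parents, "parental_pair"))
  if (nchar(query) != nchar(parents$female)) stop("query not aligned to parents")
  rq <- charToRaw(toupper(query))
  rf <- charToRaw(parents$female); rm_ <- charToRaw(parents$male)
  bases <- charToRaw(paste(DNA_BASES, collapse = ""))
  pos <- parents$informative[rq[parents$informative] %in% bases]
  state <- ifelse(rq[pos] == rf[pos], "F",
                  ifelse(rq[pos] == rm_[pos], "M", NA))
  keep <- !is.na(state)
  pos <- pos[keep]; state <- state[keep]
  n <- length(pos)
  out <- list(verdict = "uninformative", segments = NULL,
              interval = c(NA_integer_, NA_integer_), chi_square = NA_real_,
              n_informative = n, informative_positions0 = pos - 1L,
              states = state)
  class(out) <- "breakpoint_call"
  if (n < 4) return(out)

  nF <- sum(state == "F")
  # noise floor: <=1 discordant site against the best single parent
  if (min(nF, n - nF) <= 1) {
    out$verdict <- "non-recombinant"
    out$segments <- data.frame(start = 0L, end = nchar(query),
                               parent = if (nF >= n - nF) "female" else "male",
                               stringsAsFactors = FALSE)
    out$chi_square <- 0
    return(out)
  }

  isF <- state == "F"
  cumF <- cumsum(isF)
  best_k <- NA_integer_; best_chi <- -Inf
  for (k in 1:(n - 1)) {
    a <- cumF[k]            # F matches left
    b <- k - a              # M matches left
    c <- nF - a             # F matches right
    d <- (n - k) - c        # M matches right
    chi <- chisq2x2(a, b, c, d)
    if (chi > best_chi + 1e-12) {
      best_chi <- chi; best_k <- k
    }
  }
  a <- cumF[best_k]; b <- best_k - a
  c <- nF - a; d <- (n - best_k) - c
  left_parent <- if (a >= b) "female" else "male"
  right_parent <- if (c >= d) "female" else "male"
  left_purity <- max(a, b) / (a + b)
  right_purity <- max(c, d) / (c + d)
  out$chi_square <- best_chi
  if (best_chi >= chi_threshold && left_purity >= purity &&
      right_purity >= purity && left_parent != right_parent) {
    out$verdict <- "single-crossover"
    lo <- pos[best_k] - 1L       # 0-based position of last left informative site
    hi <- pos[best_k + 1] - 1L   # 0-based position of first right informative site
    out$interval <- c(lo + 1L, hi + 1L)  # half-open [lo+1, hi+1)
    out$segments <- data.frame(
      start = c(0L, out$interval[1]),
      end = c(out$interval[1], nchar(query)),
      parent = c(left_parent, right_parent), stringsAsFactors = FALSE)
  } else {
    out$verdict <- "complex"
  }
  out
}

#' @export
print.breakpoint_call <- function(x, ...) {
  cat(sprintf("<breakpoint call: %s; %d informative sites; chi-square %.2f>\n",
              x$verdict, x$n_informative,
              if (is.na(x$chi_square)) NA else x$chi_square))
  if (x$verdict == "single-crossover") {
    cat(sprintf("  %s -> %s, crossover interval [%d, %d) (0-based)\n",
                x$segments$parent[1], x$segments$parent[2],
                x$interval[1], x$interval[2]))
  }
  invisible(x)
}

#' Summarize heteroplasmy of cancer mitochondrial alleles across a cohort
#'
#' Per diseased individual, reports which of the profile's cancer
#' mitochondrial alleles are present — by curated clone support and/or by
#' qPCR detectability — and flags heteroplasmy (more than one cancer
#' mitochondrial allele), loss (a profile allele undetectable in a carrier
#' of the lineage), and mitochondrial replacement (a shared cancer
#' mitochondrial allele that is host-species-derived rather than
#' source-species-derived, judged by p-distance to species reference
#' alleles).
#'
#' @param genotypes List of `individual_genotype` objects.
#' @param profile A `lineage_profile` restricted to mitochondrial loci.
#' @param fractions Optional `allele_fraction` data frame from
#'   [allele_fraction_table()] (qPCR evidence).
#' @param species_refs Optional nested list: species -> locus -> character
#'   vector of reference mito sequences (to judge replacement).
#' @param host_species Host species name for the replacement test.
#' @param source_species Cancer source species name.
#' @param radius Near-match radius for clone evidence.
#' @return Data frame, one row per diseased individual x profile allele.
#' @export
assess_heteroplasmy <- function(genotypes, profile, fractions = NULL,
                                species_refs = NULL, host_species = NULL,
                                source_species = NULL, radius = 1) {
  diseased <- Filter(function(g) g$diagnosis == "cancer", genotypes)
  rows <- list()
  for (g in diseased) {
    for (j in seq_len(nrow(profile))) {
      lc <- profile$locus[j]
      cloned <- lc %in% names(g$calls) &&
        near_any(profile$sequence[j], alleles_of(g, lc), radius)
      qpcr <- NA
      if (!is.null(fractions)) {
        hit <- fractions$sample == g$individual_id &
          fractions$locus == lc & fractions$allele == profile$label[j]
        if (any(hit)) qpcr <- fractions$status[hit][1] %in% c("detected", "over_unity")
      }
      present <- cloned || isTRUE(qpcr)
      rows[[length(rows) + 1]] <- data.frame(
        id = g$individual_id, locus = lc, allele = profile$label[j],
        cloned = cloned, qpcr_detected = qpcr, present = present,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  # per-individual flags
  agg <- tapply(out$present, out$id, sum)
  out$heteroplasmic <- unname(agg[out$id] > 1)
  out$loss <- !out$present & unname(agg[out$id] >= 1)
  # replacement: a profile allele closer to host-species references than to
  # source-species references
  out$replacement <- FALSE
  if (!is.null(species_refs) && !is.null(host_species) &&
      !is.null(source_species)) {
    for (j in seq_len(nrow(profile))) {
      s <- profile$sequence[j]
      lc <- profile$locus[j]
      host_refs <- species_refs[[host_species]][[lc]]
      src_refs <- species_refs[[source_species]][[lc]]
      if (is.null(host_refs) || is.null(src_refs)) next
      d_host <- min(vapply(host_refs,
                           function(r) pairwise_distance(s, r), numeric(1)))
      d_src <- min(vapply(src_refs,
                          function(r) pairwise_distance(s, r), numeric(1)))
      if (d_host < d_src) {
        out$replacement[out$allele == profile$label[j] &
                          out$locus == lc] <- TRUE
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Detect a head-to-tail tandem repeat of a candidate unit
#'
#' Emulates the junction-amplification assay (outward-facing primers across
#' the repeat junction): a tandem repeat exists when the unit occurs at
#' least twice head-to-tail, i.e. the junction formed by the unit's tail
#' followed by its head is present in the sequence.  When a qPCR
#' allele-specific fraction and the true (or independently estimated) cancer
#' template fraction are supplied, the repeat copy number is also estimated
#' as their ratio — the mechanism by which allele-specific fractions exceed
#' 100%.
#'
#' @param region Sequence to scan.
#' @param unit Candidate repeat unit (length >= 20).
#' @param qpcr_fraction Optional observed allele-specific/universal fraction.
#' @param template_fraction Optional true fraction of templates carrying the
#'   allele.
#' @return List: `junction_found`, `copies_in_sequence` (max head-to-tail
#'   run), `copies_from_qpcr` (or NA).
#' @export
detect_tandem_repeat <- function(region, unit, qpcr_fraction = NULL,
                                 template_fraction = NULL) {
  if (nchar(unit) < 20) stop("candidate repeat unit shorter than 20 sites")
  hits <- gregexpr(unit, region, fixed = TRUE)[[1]]
  copies <- 0L
  if (hits[1] != -1) {
    # longest run of occurrences spaced exactly one unit length apart
    run <- 1L; copies <- 1L
    if (length(hits) > 1) {
      for (i in 2:length(hits)) {
        run <- if (hits[i] - hits[i - 1] == nchar(unit)) run + 1L else 1L
        copies <- max(copies, run)
      }
    }
  }
  junction <- copies >= 2L
  copies_qpcr <- NA_real_
  if (!is.null(qpcr_fraction) && !is.null(template_fraction) &&
      template_fraction > 0) {
    copies_qpcr <- qpcr_fraction / template_fraction
  }
  list(junction_found = junction, copies_in_sequence = copies,
       copies_from_qpcr = copies_qpcr)
}
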