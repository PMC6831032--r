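# Curation of cloned PCR products into supported allele calls.
#
# Rules applied, in order, per individual x locus:
#   1. deduplicate identical clone sequences;
#   2. absorb single-clone sequences that differ by at most the per-locus
#      collapse threshold (<0.5% of the aligned length) from an allele
#      supported by more than one clone, into the closer such allele;
#   3. discard any remaining single-clone sequence that is consistent with a
#      single-crossover PCR recombination between two multi-clone alleles of
#      the same individual.

#' Construct a clone set from raw sequences
#'
#' @param clones Named character vector of equal-length aligned clone
#'   sequences over `{A,C,G,T,-,N}`.
#' @param individual_id,locus Identifiers.
#' @return A `clone_set` object.
#' @export
clone_set <- function(clones, individual_id = "ind", locus = "locus") {
  if (length(clones) < 1) stop("a clone set needs at least one clone")
  w <- nchar(clones)
  if (length(unique(w)) != 1) {
    stop("clones have unequal lengths: ", paste(unique(w), collapse = ", "))
  }
  if (is.null(names(clones))) {
    names(clones) <- sprintf("%s_%s_c%d", individual_id, locus, seq_along(clones))
  }
  structure(list(individual_id = individual_id, locus = locus,
                 clones = toupper(clones)),
            class = "clone_set")
}

#' Deduplicate clones into (unique sequence, count) pairs
#'
#' Ordering is by descending clone count, ties broken by lexicographic
#' sequence, so the output is invariant to clone order.
#'
#' @param cs A `clone_set`.
#' @return Data frame with columns `sequence` and `count`.
#' @export
dedupe_clones <- function(cs) {
  cl <- cs$clones
  w <- nchar(cl)
  if (length(unique(w)) != 1) stop("clones have unequal lengths")
  tab <- table(cl)
  df <- data.frame(sequence = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df[order(-df$count, df$sequence), , drop = FALSE] -> df
  rownames(df) <- NULL
  df
}

#' Absorb singleton sequences into nearby supported alleles
#'
#' A sequence found in only a single clone that differs by at most the
#' locus's collapse threshold from an allele supported by more than one
#' clone is treated as a PCR/sequencing error of that allele: its clone is
#' added to the closer allele's support and the absorbed sequence recorded.
#' Singletons beyond the threshold of every supported allele are retained as
#' distinct calls.  If a singleton is within threshold of several supported
#' alleles it is absorbed into the closest; ties go to the higher-support
#' allele, then the lexicographically smaller sequence.
#'
#' @param uniques Data frame from [dedupe_clones()].
#' @param locus A [locus_spec()] (supplies `collapse_threshold`).
#' @return Data frame of allele calls: `sequence`, `support`, `singleton`,
#'   and a list-column `absorbed` of absorbed sequences.
#' @export
collapse_singletons <- function(uniques, locus) {
  thr <- locus$collapse_threshold
  multi <- uniques[uniques$count > 1, , drop = FALSE]
  singles <- uniques[uniques$count == 1, , drop = FALSE]
  calls <- data.frame(sequence = multi$sequence, support = multi$count,
                      stringsAsFactors = FALSE)
  calls$absorbed <- replicate(nrow(calls), character(0), simplify = FALSE)
  kept <- character(0)
  if (nrow(multi) > 0 && nrow(singles) > 0) {
    for (s in singles$sequence) {
      d <- hamming_to_all(s, calls$sequence)
      ok <- which(d <= thr)
      if (length(ok) > 0) {
        ord <- ok[order(d[ok], -calls$support[ok], calls$sequence[ok])]
        i <- ord[1]
        calls$support[i] <- calls$support[i] + 1L
        calls$absorbed[[i]] <- c(calls$absorbed[[i]], s)
      } else {
        kept <- c(kept, s)
      }
    }
  } else {
    kept <- singles$sequence
  }
  if (length(kept) > 0) {
    add <- data.frame(sequence = kept, support = 1L, stringsAsFactors = FALSE)
    add$absorbed <- replicate(nrow(add), character(0), simplify = FALSE)
    calls <- rbind(calls, add)
  }
  calls$singleton <- calls$support == 1L
  calls[order(-calls$support, calls$sequence), , drop = FALSE] -> calls
  rownames(calls) <- NULL
  calls
}

# Is `q` explainable as a single-crossover splice of ordered pair (a, b)?
# True iff there is one crossover point such that q matches a at every
# informative site (a != b, N excluded) left of it and b at every informative
# site right of it, with at least `min_side` informative sites supporting
# each segment (a one-site "segment" is indistinguishable from a point
# error and is handled by singleton collapse instead).
is_single_crossover <- function(q, a, b, min_side = 2L) {
  qa <- charToRaw(q); ra <- charToRaw(a); rb <- charToRaw(b)
  N <- charToRaw("N")
  inf <- which(ra != rb & ra != N & rb != N & qa != N)
  if (length(inf) < 2 * min_side) return(FALSE)
  match_a <- qa[inf] == ra[inf]
  match_b <- qa[inf] == rb[inf]
  # q must match one parent or the other at every informative site
  if (any(!match_a & !match_b)) return(FALSE)
  # not a chimera if q equals one parent across all informative sites
  if (all(match_a) || all(match_b)) return(FALSE)
  n <- length(inf)
  prefix_a <- cumsum(match_a) == seq_len(n)
  suffix_b <- rev(cumsum(rev(match_b)) == seq_len(n))
  k <- which(prefix_a[-n] & suffix_b[-1])
  k <- k[k >= min_side & (n - k) >= min_side]
  length(k) > 0
}

#' Flag and discard chimeric singleton calls
#'
#' A single-clone call is discarded iff it is consistent with a single PCR
#' recombination event between two multi-clone alleles from the same
#' individual: for some ordered pair (A, B) and one crossover point the
#' singleton equals A left of the point and B right of it at every
#' informative site, with at least two informative sites supporting each
#' segment.  Flagging requires at least two multi-clone calls to be
#' present; multi-clone calls are never discarded.
#'
#' @param calls Data frame from [collapse_singletons()].
#' @param locus A [locus_spec()] (unused by the rule itself; kept for a
#'   uniform interface).
#' @return `calls` with chimeric singletons removed; discarded sequences in
#'   `attr(, "discarded_chimeras")`.
#' @export
flag_chimeras <- function(calls, locus = NULL) {
  discarded <- character(0)
  parents_all <- calls$sequence[calls$support > 1]
  if (length(parents_all) >= 2 && any(calls$singleton)) {
    for (s in calls$sequence[calls$singleton]) {
      parents <- setdiff(parents_all, s)
      chim <- FALSE
      for (a in parents) {
        for (b in parents) {
          if (a != b && is_single_crossover(s, a, b)) {
            chim <- TRUE
            break
          }
        }
        if (chim) break
      }
      if (chim) discarded <- c(discarded, s)
    }
  }
  out <- calls[!(calls$sequence %in% discarded), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "discarded_chimeras") <- discarded
  out
}

#' Curate a clone set into allele calls
#'
#' Runs deduplication, singleton collapse and chimera discard, then assigns
#' stable allele labels (letters, in descending support order with
#' lexicographic tie-break).
#'
#' @param cs A `clone_set`.
#' @param locus A [locus_spec()].
#' @return An `allele_calls` data frame: `sequence`, `support`, `label`,
#'   `singleton`, list-column `absorbed`; attributes `individual_id`,
#'   `locus`, `discarded_chimeras`.
#' @export
call_alleles <- function(cs, locus) {
  if (length(cs$clones) == 0) stop("empty clone set")
  calls <- flag_chimeras(collapse_singletons(dedupe_clones(cs), locus), locus)
  discarded <- attr(calls, "discarded_chimeras")
  labels <- c(LETTERS, paste0("A", LETTERS))
  calls$label <- labels[seq_len(nrow(calls))]
  calls <- calls[, c("sequence", "support", "label", "singleton", "absorbed")]
  attr(calls, "individual_id") <- cs$individual_id
  attr(calls, "locus") <- cs$locus
  attr(calls, "discarded_chimeras") <- discarded
  class(calls) <- c("allele_calls", "data.frame")
  calls
}

#' @export
print.allele_calls <- function(x, ...) {
  cat(sprintf("Allele calls for %s x %s (%d alleles",
              attr(x, "individual_id") %||% "?", attr(x, "locus") %||% "?",
              nrow(x)))
  nd <- length(attr(x, "discarded_chimeras"))
  if (nd > 0) cat(sprintf(", %d chimera%s discarded", nd, if (nd > 1) "s" else ""))
  cat(")\n")
  df <- data.frame(label = x$label, support = x$support,
                   singleton = x$singleton,
                   absorbed = vapply(x$absorbed, length, integer(1)))
  print(df, row.names = FALSE)
  invisible(x)
}
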