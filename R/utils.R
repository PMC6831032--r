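# Internal sequence helpers.  Sequences are plain uppercase character strings
# over {A,C,G,T,-,N}; alignments are named character vectors of equal width.

DNA_BASES <- c("A", "C", "G", "T")

#' Hamming distance between two aligned sequences
#'
#' Counts positions at which two equal-length aligned sequences differ.  A gap
#' (`-`) versus a base counts as one difference; `N` matches anything.  This is
#' the distance used by the clone-curation rules, where alignment columns are
#' compared directly.
#'
#' @param a,b Character scalars of equal length (aligned sequences).
#' @return Integer count of differing positions.
#' @examples
#' hamming_distance("ACGT", "ACGA")   # 1
#' hamming_distance("ACGT", "ACNT")   # 0, N is a wildcard
#' @export
hamming_distance <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  if (length(ra) != length(rb)) {
    stop("sequences have unequal lengths (", length(ra), " vs ", length(rb), ")")
  }
  n <- ra == charToRaw("N") | rb == charToRaw("N")
  sum(ra != rb & !n)
}

# Vectorised Hamming from one string to many (same wildcard/gap rules).
hamming_to_all <- function(a, seqs) {
  vapply(seqs, function(s) hamming_distance(a, s), integer(1), USE.NAMES = FALSE)
}

# Random DNA sequence of length n (uses the current RNG stream).
random_seq <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Apply n_sub substitutions at distinct positions, each to a different base.
mutate_seq <- function(seq, n_sub) {
  if (n_sub == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_sub <- min(n_sub, length(chars))
  pos <- sample.int(length(chars), n_sub)
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# Splice two equal-length sequences at 1-based crossover point k:
# result = left[1..k] + right[(k+1)..L].  The switch therefore begins at
# 0-based position k.
splice_seqs <- function(left, right, k) {
  L <- nchar(left)
  stopifnot(nchar(right) == L, k >= 1L, k < L)
  paste0(substr(left, 1L, k), substr(right, k + 1L, L))
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
# All exported simulators take explicit seeds; none leaks global random state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Derive a child seed from a base seed and a stream index, kept < 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(k) %% 100000L
}

`%||%` <- function(x, y) if (is.null(x)) y else x
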