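# Independent brute-force oracles.  Deliberately naive implementations,
# kept free of any package internals they are used to check.

# Character-by-character Hamming count with the same gap/N conventions:
# gap-vs-base differs, N matches anything.
oracle_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  n <- 0L
  for (i in seq_along(ca)) {
    if (ca[i] == "N" || cb[i] == "N") next
    if (ca[i] != cb[i]) n <- n + 1L
  }
  n
}

# p-distance with pairwise deletion of non-ACGT sites.
oracle_pdist <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  sum(ca[ok] != cb[ok]) / sum(ok)
}

# Exhaustive single-crossover check: try every split position of the whole
# sequence; q must equal a left of it and b right of it at every site where
# a and b differ, with >= min_side informative sites on each side.
oracle_chimera <- function(q, a, b, min_side = 2L) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  cq <- strsplit(q, "")[[1]]
  inf <- which(ca != cb)
  if (length(inf) < 2 * min_side) return(FALSE)
  for (k in seq_len(length(cq) - 1)) {
    left <- inf[inf <= k]
    right <- inf[inf > k]
    if (length(left) < min_side || length(right) < min_side) next
    if (all(cq[left] == ca[left]) && all(cq[right] == cb[right])) return(TRUE)
  }
  FALSE
}

# Midpoint-rooting property: after rooting, the deepest leaf depth equals
# half the tree diameter (maximum leaf-to-leaf path length).
oracle_midpoint_ok <- function(rooted, tol = 1e-8) {
  d <- ape::cophenetic.phylo(rooted)
  diameter <- max(d)
  depths <- ape::node.depth.edgelength(rooted)[seq_len(ape::Ntip(rooted))]
  abs(max(depths) - diameter / 2) < tol
}

# 2x2 chi-square statistic via stats::chisq.test (no continuity correction).
oracle_chisq <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), 2, 2)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(0)
  unname(suppressWarnings(stats::chisq.test(m, correct = FALSE)$statistic))
}

# Brute-force maximum chi-square split scan over the informative-site match
# states of a query against a parental pair.
oracle_split_scan <- function(query, female, male) {
  cf <- strsplit(female, "")[[1]]
  cm <- strsplit(male, "")[[1]]
  cq <- strsplit(query, "")[[1]]
  pos <- which(cf != cm & cf %in% c("A","C","G","T") & cm %in% c("A","C","G","T") &
                 cq %in% c("A","C","G","T"))
  st <- ifelse(cq[pos] == cf[pos], "F", ifelse(cq[pos] == cm[pos], "M", NA))
  pos <- pos[!is.na(st)]; st <- st[!is.na(st)]
  n <- length(st)
  if (n < 2) return(NA_real_)
  best <- -Inf
  for (k in 1:(n - 1)) {
    a <- sum(st[1:k] == "F"); b <- k - a
    c <- sum(st[(k + 1):n] == "F"); d <- (n - k) - c
    best <- max(best, oracle_chisq(a, b, c, d))
  }
  best
}
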