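# Distance-based phylogenetics for allele alignments.  Trees are built by
# neighbor joining on p- or Jukes-Cantor distances with nonparametric
# bootstrap supports, rooted at the midpoint; claims made downstream are
# clade-membership claims (which species' alleles a cancer lineage nests
# within), which are robust to substitution-model choice at these
# divergences.  Trees are `ape::phylo` objects throughout.

#' Pairwise distance between two aligned sequences
#'
#' p-distance is differences over compared sites, where only positions with
#' an unambiguous base (A/C/G/T) in both sequences are compared — gaps and N
#' are treated as missing data and excluded pairwise.  The Jukes-Cantor
#' distance is `-(3/4) log(1 - 4p/3)`; it is undefined for `p >= 0.75`, in
#' which case `NaN` is returned with a warning.
#'
#' @param a,b Aligned sequences (equal length).
#' @param model `"p"` or `"JC"`.
#' @return Distance in substitutions/site.
#' @export
pairwise_distance <- function(a, b, model = c("p", "JC")) {
  model <- match.arg(model)
  ra <- charToRaw(toupper(a)); rb <- charToRaw(toupper(b))
  if (length(ra) != length(rb)) stop("sequences have unequal lengths")
  bases <- charToRaw(paste(DNA_BASES, collapse = ""))
  ok <- (ra %in% bases) & (rb %in% bases)
  n <- sum(ok)
  if (n == 0) stop("no comparable sites")
  p <- sum(ra[ok] != rb[ok]) / n
  if (model == "p") return(p)
  if (p >= 0.75) {
    warning("p-distance >= 0.75: Jukes-Cantor distance undefined")
    return(NaN)
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Distance matrix for an alignment
#'
#' @param alignment Named character vector of equal-length sequences (or an
#'   `allele_alignment`).
#' @param model `"p"` or `"JC"`.
#' @return A `dist` object labelled by sequence name.
#' @export
alignment_distances <- function(alignment, model = c("p", "JC")) {
  model <- match.arg(model)
  seqs <- if (inherits(alignment, "allele_alignment")) alignment$seqs else alignment
  n <- length(seqs)
  m <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- pairwise_distance(seqs[i], seqs[j], model)
    }
  }
  stats::as.dist(m)
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining (via [ape::nj()]) on a symmetric non-negative
#' distance matrix.  Negative branch lengths arising from noise are clamped
#' to zero.
#'
#' @param d A `dist` or symmetric matrix.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 3) stop("neighbor joining needs at least 3 leaves")
  if (any(m < 0) || any(abs(m - t(m)) > 1e-12)) {
    stop("distance matrix must be symmetric and non-negative")
  }
  tr <- ape::nj(stats::as.dist(m))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Root a tree at the midpoint
#'
#' Inserts the root at the midpoint of the longest leaf-to-leaf path.  With
#' all-zero branch lengths the midpoint is arbitrary; the returned root is
#' flagged with a warning.
#'
#' @param t A `phylo` tree with branch lengths.
#' @return A rooted `phylo` tree.
#' @export
midpoint_root <- function(t) {
  if (is.null(t$edge.length)) stop("midpoint rooting needs branch lengths")
  if (ape::Ntip(t) < 2) stop("midpoint rooting needs at least 2 leaves")
  if (all(t$edge.length == 0)) {
    warning("all branch lengths are zero; midpoint root is arbitrary")
    return(phangorn::midpoint(t))
  }
  phangorn::midpoint(t)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports bipartition frequencies (percent) as internal node
#' labels on the full-data tree.  In rendered output, supports below
#' `collapse_below` are suppressed (shown as empty labels).
#'
#' @param alignment Named character vector (or `allele_alignment`).
#' @param n_reps Bootstrap replicates (>= 1).
#' @param model Distance model, `"p"` or `"JC"`.
#' @param seed Integer seed.
#' @return The NJ tree with `node.label` set to support percentages.
#' @export
bootstrap_supports <- function(alignment, n_reps = 100, model = "JC",
                               seed = NULL) {
  seqs <- if (inherits(alignment, "allele_alignment")) alignment$seqs else alignment
  stopifnot(n_reps >= 1)
  base <- nj_tree(alignment_distances(seqs, model))
  mat <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  L <- ncol(mat)
  with_seed(seed, {
    reps <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      boot <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
      reps[[r]] <- nj_tree(alignment_distances(boot, model))
    }
    counts <- ape::prop.clades(base, reps, rooted = FALSE)
    counts[is.na(counts)] <- 0
    base$node.label <- as.character(round(100 * counts / n_reps))
    base
  })
}

#' Hide low bootstrap supports for rendering
#'
#' @param t A `phylo` tree with numeric `node.label` supports.
#' @param collapse_below Supports strictly below this value are blanked
#'   (default 50).
#' @return The tree with suppressed labels.
#' @export
collapse_low_support <- function(t, collapse_below = 50) {
  if (is.null(t$node.label)) return(t)
  sup <- suppressWarnings(as.numeric(t$node.label))
  t$node.label[!is.na(sup) & sup < collapse_below] <- ""
  t
}

#' Assign the species of origin of a cancer lineage from a rooted tree
#'
#' The species of origin is read off the minimal clade containing all of the
#' lineage's cancer-associated alleles: the species of the normal alleles in
#' that clade.  Leaves belonging to other cancer lineages, and known
#' introgressed/hybrid alleles, are excluded from the computation (dropped
#' from the tree).  Two lineages are called independent when their cancer
#' alleles do not form an exclusive clade together.
#'
#' @param t Rooted `phylo` tree.
#' @param cancer_labels Leaf labels of the focal lineage's cancer alleles.
#' @param species_map Named character vector: leaf label -> species (normal
#'   alleles only need apply; cancer leaves may be absent or NA).
#' @param exclude Leaf labels to drop before the computation (other-lineage
#'   cancer alleles, known hybrids).
#' @return List: `species` (verdict, or `"unresolved"` when the cancer
#'   alleles span the root), `clade_species` (species tallies inside the
#'   minimal clade), `n_clade_leaves`.
#' @export
assign_source_species <- function(t, cancer_labels, species_map,
                                  exclude = character(0)) {
  stopifnot(all(cancer_labels %in% t$tip.label))
  drop <- setdiff(intersect(exclude, t$tip.label), cancer_labels)
  if (length(drop) > 0) t <- ape::drop.tip(t, drop)
  if (length(cancer_labels) == 1) {
    # nearest normal leaf decides
    d <- ape::cophenetic.phylo(t)[cancer_labels, ]
    d <- d[setdiff(names(d), cancer_labels)]
    sp <- unname(species_map[names(which.min(d))])
    return(list(species = sp, clade_species = stats::setNames(1L, sp),
                n_clade_leaves = 2L))
  }
  mrca <- ape::getMRCA(t, cancer_labels)
  root <- ape::Ntip(t) + 1L
  if (is.null(mrca) || mrca == root) {
    return(list(species = "unresolved", clade_species = integer(0),
                n_clade_leaves = NA_integer_))
  }
  clade <- ape::extract.clade(t, mrca)$tip.label
  normals <- setdiff(clade, cancer_labels)
  if (length(normals) == 0) {
    # widen: parent clade of the mrca
    parent <- t$edge[t$edge[, 2] == mrca, 1]
    clade <- ape::extract.clade(t, parent)$tip.label
    normals <- setdiff(clade, cancer_labels)
  }
  tab <- sort(table(unname(species_map[normals])), decreasing = TRUE)
  list(species = if (length(tab) > 0) names(tab)[1] else "unresolved",
       clade_species = tab, n_clade_leaves = length(clade))
}

#' Test whether two cancer lineages are phylogenetically independent
#'
#' @param t Rooted `phylo` tree.
#' @param labels_a,labels_b Leaf labels of the two lineages' cancer alleles.
#' @return `TRUE` when the union of the two lineages' alleles does not form
#'   an exclusive clade (supporting independent origins).
#' @export
lineages_independent <- function(t, labels_a, labels_b) {
  both <- union(labels_a, labels_b)
  stopifnot(all(both %in% t$tip.label))
  mrca <- ape::getMRCA(t, both)
  if (is.null(mrca)) return(TRUE)
  clade <- ape::extract.clade(t, mrca)$tip.label
  !setequal(clade, both)
}
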